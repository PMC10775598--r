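"fraction_id","delivered"
"f01","adaptive"
"f02","adaptive"
"f03","adaptive"
"f04","adaptive"
"f05","adaptive"
"f06","adaptive"
"f07","adaptive"
"f08","adaptive"
"f09","adaptive"
"f10","adaptive"
"f11","adaptive"
"f12","adaptive"
"f13","adaptive"
"f14","adaptive"
"f15","adaptive"
"f16","adaptive"
"f17","adaptive"
"f18","adaptive"
"f19","adaptive"
"f20","adaptive"
"f21","adaptive"
"f22","adaptive"
"f23","adaptive"
"f24","adaptive"
"f25","adaptive"
"f26","adaptive"
"f27","adaptive"
"f28","adaptive"
"f29","adaptive"
"f30","adaptive"
"f31","scheduled"
"f32","scheduled"
"f33","scheduled"
"f34","scheduled"
"f35","scheduled"
"f36","scheduled"
"f37","scheduled"
"f38","scheduled"
"f39","scheduled"
"f40","scheduled"
"f41","scheduled"
"f42","scheduled"
"f43","scheduled"
"f44","scheduled"
"f45","scheduled"
"f46","scheduled"
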