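"patient_id","setting","site","art","art_course"
"pt01","definitive","oropharyngeal",FALSE,NA
"pt02","definitive","oropharyngeal",FALSE,NA
"pt03","definitive","oropharyngeal",FALSE,NA
"pt04","definitive","oropharyngeal",FALSE,NA
"pt05","definitive","oropharyngeal",FALSE,NA
"pt06","definitive","oropharyngeal",FALSE,NA
"pt07","definitive","oropharyngeal",FALSE,NA
"pt08","definitive","oropharyngeal",FALSE,NA
"pt09","definitive","oropharyngeal",FALSE,NA
"pt10","definitive","oropharyngeal",FALSE,NA
"pt11","definitive","oropharyngeal",FALSE,NA
"pt12","definitive","oropharyngeal",FALSE,NA
"pt13","definitive","oral_cavity",FALSE,NA
"pt14","definitive","oral_cavity",FALSE,NA
"pt15","definitive","oral_cavity",FALSE,NA
"pt16","definitive","oral_cavity",FALSE,NA
"pt17","definitive","oral_cavity",FALSE,NA
"pt18","definitive","oral_cavity",FALSE,NA
"pt19","definitive","oral_cavity",FALSE,NA
"pt20","definitive","oral_cavity",FALSE,NA
"pt21","definitive","oral_cavity",FALSE,NA
"pt22","definitive","oral_cavity",FALSE,NA
"pt23","definitive","oral_cavity",FALSE,NA
"pt24","definitive","oral_cavity",FALSE,NA
"pt25","definitive","oral_cavity",FALSE,NA
"pt26","definitive","larynx",FALSE,NA
"pt27","definitive","larynx",FALSE,NA
"pt28","definitive","other",FALSE,NA
"pt29","definitive","oropharyngeal",TRUE,"boost"
"pt30","definitive","oral_cavity",TRUE,"boost"
"pt31","postoperative","oropharyngeal",FALSE,NA
"pt32","postoperative","oropharyngeal",FALSE,NA
"pt33","postoperative","oropharyngeal",FALSE,NA
"pt34","postoperative","oropharyngeal",FALSE,NA
"pt35","postoperative","oropharyngeal",FALSE,NA
"pt36","postoperative","oropharyngeal",FALSE,NA
"pt37","postoperative","oropharyngeal",FALSE,NA
"pt38","postoperative","oropharyngeal",FALSE,NA
"pt39","postoperative","oropharyngeal",FALSE,NA
"pt40","postoperative","oropharyngeal",FALSE,NA
"pt41","postoperative","oral_cavity",FALSE,NA
"pt42","postoperative","oral_cavity",FALSE,NA
"pt43","postoperative","oral_cavity",FALSE,NA
"pt44","postoperative","oral_cavity",FALSE,NA
"pt45","postoperative","oral_cavity",FALSE,NA
"pt46","postoperative","oral_cavity",FALSE,NA
"pt47","postoperative","oral_cavity",FALSE,NA
"pt48","postoperative","hypopharyngeal",FALSE,NA
"pt49","postoperative","larynx",FALSE,NA
"pt50","postoperative","other",FALSE,NA
"pt51","postoperative","other",FALSE,NA
"pt52","postoperative","oropharyngeal",TRUE,"boost"
"pt53","postoperative","oropharyngeal",TRUE,"boost"
"pt54","postoperative","oropharyngeal",TRUE,"boost"
"pt55","postoperative","oropharyngeal",TRUE,"boost"
"pt56","postoperative","oral_cavity",TRUE,"boost"
"pt57","postoperative","oropharyngeal",TRUE,"initial"
"pt58","postoperative","oropharyngeal",TRUE,"initial"
"pt59","postoperative","oral_cavity",TRUE,"initial"
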