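subcriterion,metric,kind,numerator,denominator,units
SH1,% of ED wards with suitable infrastructure status,ratio_percent,ED wards with suitable infrastructure,total ED wards,percent
SH2,% of ED wards without suitable illumination and cleansing,ratio_percent,ED wards without suitable illumination and cleansing,total ED wards,percent
SH3,Availability of sanitary installations,binary,ready to use,NA,indicator
SH4,Delineation of ED areas,binary,delineated,NA,indicator
SH5,Number of available beds in the ED,count,beds available for COVID-19 patients,NA,beds
SH6,% of ready-to-use healthcare equipment,ratio_percent,ready-to-use healthcare equipment,total medical devices,percent
SH7,% of medical equipment pertinent to COVID-19 requirements,ratio_percent,pertinent medical devices,total medical devices,percent
SH8,% of flawed medical equipment,ratio_percent,flawed medical equipment,total medical devices,percent
SH9,Design of medical care procedures for COVID-19 management,binary,designed,NA,indicator
SH10,% of widespread COVID-19-related procedures and protocols,ratio_percent,widespread procedures and protocols,total procedures and protocols,percent
SH11,Percentage of monitored adverse events in the ED,ratio_percent,supervised adverse events,total adverse events,percent
SH12,Average turnaround time for radiology outcomes,mean_interval,total radiology turnaround time,annual number of radiology tests,minutes
SH13,Average turnaround time for lab test results,mean_interval,total lab turnaround time,annual number of lab tests,minutes
SH14,Average patient transfer time from ED to hospitalization bed,mean_interval,total transfer delay,annual number of transferred patients,minutes
SH15,Average lead time for medication delivery,mean_interval,total medication lead time,annual number of medication orders,minutes
SH16,Availability of ambulances satisfying WHO COVID-19 standards,binary,available,NA,indicator
SH17,Implementation of sterilization protocols against COVID-19,binary,implemented,NA,indicator
SH18,Number of functioning non-core activities,count,functioning non-core activities,NA,activities
SH19,Amount of available positions for ED specialists,count,specialists necessitated to balance COVID-19 demand,NA,positions
SH20,Amount of available positions for ED general physicians,count,general physicians necessitated to balance COVID-19 demand,NA,positions
SH21,Percentage of medical staff with ALS certification,ratio_percent,certified medical staff,total medical staff,percent
SH22,Amount of available positions for ED nurses,count,nurses necessitated to balance COVID-19 demand,NA,positions
SH23,Availability of accessories and instrumentation for COVID-19 management,count,accessories and instruments necessitated to balance demand,NA,items
SH24,Inventory service level (medical consumables),ratio_percent,satisfied orders of medical consumables,total orders,percent
SH25,Inventory service level (medication),ratio_percent,satisfied medication orders,total medication orders,percent
SH26,Bed occupation ratio,ratio_percent,ED beds occupied by COVID-19 patients,total ED beds assigned to COVID-19 patients,percent
SH27,Average doctor's waiting time,mean_interval,total consultation waiting time,annual number of COVID-19 patients,minutes
SH28,Patient satisfaction ratio,ratio_percent,satisfied COVID-19 patients,admitted COVID-19 patients,percent
SH29,Mean length of stay in the ED,mean_interval,total length of stay,admitted COVID-19 patients,hours
SH30,72-h readmission rate,ratio_percent,readmitted COVID-19 patients within 72 h,admitted COVID-19 patients,percent
SH31,Mean waiting time for triage categorization,mean_interval,total triage waiting time,admitted COVID-19 patients,minutes
SH32,Average monthly number of intra-hospital COVID-19 infections,mean_interval,annual intra-hospital COVID-19 infections,12,events per month
SH33,Average monthly number of medication mistakes,mean_interval,annual medication mistakes,12,events per month
SH34,Average monthly number of COVID-19 diagnosis mistakes,mean_interval,annual diagnosis mistakes,12,events per month
SH35,Average monthly number of patient misidentification mistakes,mean_interval,annual misidentification mistakes,12,events per month
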