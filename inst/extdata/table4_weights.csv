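code,parent,name,level,local,overall,cr
goal,NA,ED performance,goal,NA,NA,0.058
H1,goal,ER facilities,criterion,NA,0.144,0.046
H2,goal,Healthcare equipment,criterion,NA,0.119,0.024
H3,goal,Procedures and protocols,criterion,NA,0.117,0.003
H4,goal,Assisting processes,criterion,NA,0.134,0.046
H5,goal,Human talent,criterion,NA,0.137,0.062
H6,goal,Supply of medicines and medical accessories,criterion,NA,0.109,0.057
H7,goal,Quality in healthcare,criterion,NA,0.123,0.097
H8,goal,Patient safety,criterion,NA,0.119,0.020
SH1,H1,Physical status,subcriterion,0.197,0.028,NA
SH2,H1,Airing and lighting,subcriterion,0.202,0.029,NA
SH3,H1,Sanitary installation,subcriterion,0.220,0.032,NA
SH4,H1,Delineation of emergency areas,subcriterion,0.179,0.026,NA
SH5,H1,Bed availability,subcriterion,0.201,0.029,NA
SH6,H2,Availability of healthcare equipment,subcriterion,0.316,0.038,NA
SH7,H2,Appropriateness of medical equipment,subcriterion,0.326,0.039,NA
SH8,H2,Medical equipment condition,subcriterion,0.358,0.043,NA
SH9,H3,Presence of medical care procedures,subcriterion,0.333,0.039,NA
SH10,H3,Diffusion of procedures and protocols,subcriterion,0.333,0.039,NA
SH11,H3,Compliance with medical care protocols and procedures,subcriterion,0.333,0.039,NA
SH12,H4,Efficacy of radiology process,subcriterion,0.140,0.019,NA
SH13,H4,Efficacy of clinical lab,subcriterion,0.148,0.020,NA
SH14,H4,Efficacy of hospitalization process,subcriterion,0.121,0.016,NA
SH15,H4,Efficacy of pharmaceutical service,subcriterion,0.143,0.019,NA
SH16,H4,Transportation efficacy,subcriterion,0.140,0.019,NA
SH17,H4,Efficacy of sterilization process,subcriterion,0.141,0.019,NA
SH18,H4,Efficacy of non-core activities,subcriterion,0.168,0.022,NA
SH19,H5,Number of specialists,subcriterion,0.214,0.029,NA
SH20,H5,Number of general practitioners,subcriterion,0.259,0.035,NA
SH21,H5,Certification in Advanced Life Support,subcriterion,0.267,0.037,NA
SH22,H5,Number of nurses,subcriterion,0.260,0.036,NA
SH23,H6,Readiness of accessories and instrumentation,subcriterion,0.228,0.025,NA
SH24,H6,Supplies fill rate,subcriterion,0.256,0.028,NA
SH25,H6,Medication fill rate,subcriterion,0.231,0.025,NA
SH26,H6,Bed occupancy rate,subcriterion,0.286,0.031,NA
SH27,H7,Mean physician waiting time,subcriterion,0.198,0.024,NA
SH28,H7,Patient satisfaction,subcriterion,0.208,0.026,NA
SH29,H7,Mean length of stay,subcriterion,0.201,0.025,NA
SH30,H7,Re-entry rate,subcriterion,0.200,0.025,NA
SH31,H7,Waiting time for triage categorization,subcriterion,0.193,0.024,NA
SH32,H8,Hospital-obtained infections,subcriterion,0.239,0.028,NA
SH33,H8,Medication mistakes,subcriterion,0.244,0.029,NA
SH34,H8,Clinical diagnosis mistakes,subcriterion,0.266,0.032,NA
SH35,H8,Patient identification errors,subcriterion,0.251,0.030,NA
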