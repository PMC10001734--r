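code,cluster,name,prominence,relation,role
H1,criteria,ER facilities,16.790,0.740,dispatcher
SH1,H1,Physical status,10.407,-0.721,receiver
SH2,H1,Airing and lighting,9.528,0.408,dispatcher
SH3,H1,Sanitary installation,9.350,0.323,dispatcher
SH4,H1,Delineation of emergency areas,9.782,0.374,dispatcher
SH5,H1,Bed availability,10.115,-0.384,receiver
H2,criteria,Healthcare equipment,17.685,-0.183,receiver
SH6,H2,Availability of healthcare equipment,32.646,-1.078,receiver
SH7,H2,Appropriateness of medical equipment,32.187,0.618,dispatcher
SH8,H2,Medical equipment condition,32.335,0.459,dispatcher
H3,criteria,Procedures and protocols,18.239,0.083,dispatcher
SH9,H3,Presence of medical care procedures,56.750,0.759,dispatcher
SH10,H3,Diffusion of procedures and protocols,56.223,0.754,dispatcher
SH11,H3,Compliance with medical care protocols and procedures,55.447,-1.513,receiver
H4,criteria,Assisting processes,17.445,0.349,dispatcher
SH12,H4,Efficacy of radiology process,10.489,0.056,dispatcher
SH13,H4,Efficacy of clinical lab,10.316,0.208,dispatcher
SH14,H4,Efficacy of hospitalization process,11.664,-0.463,receiver
SH15,H4,Efficacy of pharmaceutical service,10.365,-0.030,receiver
SH16,H4,Transportation efficacy,10.064,0.324,dispatcher
SH17,H4,Efficacy of sterilization process,9.842,0.044,dispatcher
SH18,H4,Efficacy of non-core activities,10.212,-0.139,receiver
H5,criteria,Human talent,17.494,0.195,dispatcher
SH19,H5,Number of specialists,32.926,0.138,dispatcher
SH20,H5,Number of general practitioners,33.599,0.844,dispatcher
SH21,H5,Certification in Advanced Life Support,32.871,-1.075,receiver
SH22,H5,Number of nurses,32.420,0.093,dispatcher
H6,criteria,Supply of medicines and medical accessories,17.536,-0.157,receiver
SH23,H6,Readiness of accessories and instrumentation,22.788,0.649,dispatcher
SH24,H6,Supplies fill rate,22.903,-1.280,receiver
SH25,H6,Medication fill rate,22.689,-0.196,receiver
SH26,H6,Bed occupancy rate,22.370,0.828,dispatcher
H7,criteria,Quality in healthcare,18.649,-0.683,receiver
SH27,H7,Mean physician waiting time,49.070,0.879,dispatcher
SH28,H7,Patient satisfaction,47.439,-1.265,receiver
SH29,H7,Mean length of stay,49.301,0.298,dispatcher
SH30,H7,Re-entry rate,48.133,0.320,dispatcher
SH31,H7,Waiting time for triage categorization,47.607,-0.232,receiver
H8,criteria,Patient safety,19.275,-0.343,receiver
SH32,H8,Hospital-obtained infections,15.163,-0.313,receiver
SH33,H8,Medication mistakes,16.116,-0.734,receiver
SH34,H8,Clinical diagnosis mistakes,15.317,-0.182,receiver
SH35,H8,Patient identification errors,14.805,1.229,dispatcher
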