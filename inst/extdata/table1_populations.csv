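accession,population
IC-0627004,Assam
IC-0627019,Manipur
IC-0627018,Manipur
IC-0627017,Manipur
IC-0627016,Manipur
IC-0627006,Assam
IC-0627005,Assam
IC-0627003,Assam
IC-0627002,Assam
IC-0626993,Arunachal Pradesh
IC-0626991,Meghalaya
IC-0627064,Assam
IC-0627065,Assam
IC-0627063,Assam
IC-0627062,Assam
IC-0627058,Assam
IC-0627057,Assam
IC-0627056,Assam
IC-0627052,Assam
IC-0627051,Assam
IC-0627050,Assam
IC-0627049,Assam
IC-0627048,Assam
IC-0627047,Assam
IC-0627046,Assam
IC-0627045,Assam
IC-0627044,Assam
IC-0627042,Assam
IC-0627041,Assam
IC-0627040,Assam
IC-0627039,Assam
IC-0627038,Assam
IC-0627037,Assam
IC-0627036,Assam
IC-0627033,Assam
IC-0627035,Assam
IC-0627034,Assam
IC-0627032,Assam
IC-0627031,Assam
IC-0627028,Manipur
IC-0627030,Manipur
IC-0627026,Manipur
IC-0627027,Manipur
IC-0627024,Arunachal Pradesh
IC-0627025,Arunachal Pradesh
IC-0627023,Arunachal Pradesh
IC-0627022,Arunachal Pradesh
IC-0627021,Arunachal Pradesh
IC-0627054,Assam
IC-0627043,Assam
IC-0626995,Arunachal Pradesh
IC-0627060,Assam
IC-0627055,Assam
IC-0626994,Arunachal Pradesh
IC-0627059,Assam
IC-0627012,Assam
IC-0626998,Assam
IC-0627013,Meghalaya
IC-0627001,Assam
IC-0627029,Manipur
IC-0627009,Assam
IC-0627014,Assam
IC-0626996,Arunachal Pradesh
IC-0626999,Assam
IC-0626997,Assam
IC-0627000,Assam
IC-0627011,Assam
IC-0627061,Assam
IC-0626992,Arunachal Pradesh
IC-0627053,Assam
IC-0627007,Assam
IC-0627008,Assam
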