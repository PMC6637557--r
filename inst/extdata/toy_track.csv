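"whale_id","date","lon","lat","ci_lon_lo","ci_lon_hi","ci_lat_lo","ci_lat_hi","bmode","depth_m"
"T1","2000-06-29",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-06-30",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-01",-114,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-02",-114,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-03",-114,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-04",-120,35,-122,-118,34.8,35.2,1.1,500
"T1","2000-07-05",-120,35,-122,-118,34.8,35.2,1.9,500
"T1","2000-07-06",-120,35,-120.2,-119.8,34.8,35.2,1.5,500
"T1","2000-07-07",-120,35,-120.2,-119.8,34.8,35.2,1.5,500
"T1","2000-07-08",-120,35,-120.2,-119.8,34.8,35.2,1.5,500
"T1","2000-07-09",-120,35,-120.2,-119.8,34.8,35.2,1.5,500
"T1","2000-07-10",-120,35,-120.2,-119.8,34.8,35.2,1.1,2500
"T1","2000-07-11",-120,35,-120.2,-119.8,34.8,35.2,1.9,2500
"T1","2000-07-12",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-13",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-14",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-15",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-16",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-17",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-18",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-19",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-20",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-21",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-22",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-23",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-24",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-25",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-26",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
"T1","2000-07-27",-120,35,-120.2,-119.8,34.8,35.2,1.9,500
"T1","2000-07-28",-120,35,-120.2,-119.8,34.8,35.2,1.1,500
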