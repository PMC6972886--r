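state,bond,group,field_MV_cm,dipole_D
RS,1,bulk_water,-6.72,-6.15
RS,1,complexed_water,40.81,-6.15
RS,1,cage,-0.21,-6.15
RS,2,bulk_water,-6.87,-2.83
RS,2,complexed_water,-7.97,-2.83
RS,2,cage,-14.13,-2.83
TS,1,bulk_water,-51.63,2.05
TS,1,complexed_water,19.30,2.05
TS,1,cage,27.27,2.05
TS,2,bulk_water,-31.37,0.71
TS,2,complexed_water,22.27,0.71
TS,2,cage,9.95,0.71
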