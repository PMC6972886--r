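state,bond,group,field_MV_cm,dipole_D
RS,1,bulk_water,-21.49,-6.15
RS,1,complexed_water,59.73,-6.15
RS,2,bulk_water,-12.75,-2.83
RS,2,complexed_water,-14.89,-2.83
TS,1,bulk_water,-4.55,-1.26
TS,1,complexed_water,9.63,-1.26
TS,2,bulk_water,-15.81,3.67
TS,2,complexed_water,-21.2,3.67
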