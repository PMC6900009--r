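cohort,compartment,sequence,t1_ms
pig,blood,MOLLI 5(3b)3,1600
pig,blood,MOLLI 5(3s)3,1620
pig,blood,MOLLI 5s(3s)3s,1660
pig,blood,SASHA,1820
pig,myocardium,MOLLI 5(3b)3,960
pig,myocardium,MOLLI 5(3s)3,980
pig,myocardium,MOLLI 5s(3s)3s,980
pig,myocardium,SASHA,1170
volunteer,blood,MOLLI 5(3b)3,1510
volunteer,blood,MOLLI 5(3s)3,1510
volunteer,blood,MOLLI 5s(3s)3s,1510
volunteer,blood,SASHA,1630
volunteer,myocardium,MOLLI 5(3b)3,980
volunteer,myocardium,MOLLI 5(3s)3,980
volunteer,myocardium,MOLLI 5s(3s)3s,980
volunteer,myocardium,SASHA,1220
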