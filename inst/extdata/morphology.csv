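species,f,b,m_b,m_w,S_w,AR,C_db
Peregrine falcon (male),5.1,87.3,528,32,8.97,8.49,0.16
Peregrine falcon (female),4.7,98.4,771,49,11.83,8.18,0.16
Eurasian blue tit,14,20,9.5,0.48,0.89,4.48,0.43
Common chaffinch,15.5,25,19.9,1.1,0.87,7.13,0.43
Common swift,8.3,39.2,42,2.1,1.57,9.81,0.35
Common starling,10.5,39,70,3.7,2.41,6.3,0.41
Rock dove,6.7,80,293,22.5,7.75,8.25,0.35
Mallard,6.2,86.2,995,70,9.27,8.01,0.35
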