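molecule,site,stereopath,multiplicity,stage,g_hartree,printed_fraction,printed_percent,printed_drg,printed_dgact,suspect
beta-pinene,alpha,none,2,III,-1975.973971,0,0,28.1,15.3,FALSE
beta-pinene,alpha,none,4,III,-1975.973075,0,0,10.8,12.8,FALSE
beta-pinene,delta,trans,2,III,-1976.009716,0.534,53.4,-8.3,10.8,FALSE
beta-pinene,delta,cis,2,III,-1976.009578,0.461,46.1,-7.05,12.4,FALSE
beta-pinene,delta,cis,4,III,-1976.004151,0.00147,0.147,-2.64,13.6,FALSE
beta-pinene,delta,trans,4,III,-1976.004891,0.00321,0.321,-5.08,9.87,FALSE
beta-pinene,delta,cis,6,III,-1976.000132,0,0,-9.18,12.8,FALSE
beta-pinene,delta,trans,6,III,-1976.001255,0,0,-11.5,10.1,FALSE
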