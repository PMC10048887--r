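molecule,site,stereopath,multiplicity,stage,g_hartree,printed_fraction,printed_percent,printed_drg,printed_dgact,suspect
beta-pinene,alpha,none,2,I,-1976.037587,0.49,48.77,28.1,15.3,FALSE
beta-pinene,alpha,none,4,I,-1976.030510,0,0.03,10.8,12.8,FALSE
beta-pinene,delta,trans,2,I,-1976.035861,0.08,7.83,-8.3,10.8,FALSE
beta-pinene,delta,cis,2,I,-1976.036419,0.14,14.14,-7.05,12.4,FALSE
beta-pinene,delta,cis,4,I,-1976.037104,0.29,29.23,-2.64,13.6,FALSE
beta-pinene,delta,trans,4,I,-1976.014863,0,0,-5.08,9.87,FALSE
beta-pinene,delta,cis,6,I,-1976.015837,0,0,-9.18,12.8,FALSE
beta-pinene,delta,trans,6,I,-1976.014863,0,0,-11.5,10.1,FALSE
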