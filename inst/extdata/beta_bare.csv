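molecule,site,stereopath,stage,g_hartree,printed_kcal
beta-pinene,alpha,none,bare-radical,-389.784833,21.9
beta-pinene,gamma,none,bare-radical,-389.770224,31.1
beta-pinene,delta,none,bare-radical,-389.819707,0
beta-pinene,epsilon,none,bare-radical,-389.797584,13.9
beta-pinene,zeta,none,bare-radical,-389.786313,20.9
beta-pinene,theta,none,bare-radical,-389.788711,19.4
beta-pinene,iota,none,bare-radical,-389.789920,18.7
beta-pinene,kappa,none,bare-radical,-389.790510,18.3
beta-pinene,alpha,none,bare-hydroxylated,-465.653831,0.57
beta-pinene,gamma,none,bare-hydroxylated,-465.649621,3.21
beta-pinene,delta,cis,bare-hydroxylated,-465.645132,6.03
beta-pinene,delta,trans,bare-hydroxylated,-465.644727,6.28
beta-pinene,epsilon,cis,bare-hydroxylated,-465.6451796,6.00
beta-pinene,epsilon,trans,bare-hydroxylated,-465.6473512,4.63
beta-pinene,zeta,none,bare-hydroxylated,-465.6547380,0
beta-pinene,theta,none,bare-hydroxylated,-465.6488230,3.71
beta-pinene,iota,none,bare-hydroxylated,-465.6375598,10.78
beta-pinene,kappa,none,bare-hydroxylated,-465.6399752,9.26
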