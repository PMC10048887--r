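molecule,site,stereopath,stage,g_hartree,printed_kcal
alpha-pinene,alpha,none,bare-radical,-389.788789,21.7
alpha-pinene,gamma,none,bare-radical,-389.819706,2.27
alpha-pinene,delta,none,bare-radical,-389.777607,28.7
alpha-pinene,epsilon,none,bare-radical,-389.823321,0
alpha-pinene,zeta,none,bare-radical,-389.790994,20.3
alpha-pinene,theta,none,bare-radical,-389.794206,18.3
alpha-pinene,iota,none,bare-radical,-389.795916,17.2
alpha-pinene,kappa,none,bare-radical,-389.796285,17
alpha-pinene,alpha,none,bare-hydroxylated,-465.658506,1.4
alpha-pinene,gamma,none,bare-hydroxylated,-465.645667,9.45
alpha-pinene,delta,none,bare-hydroxylated,-465.660286,0.28
alpha-pinene,epsilon,cis,bare-hydroxylated,-465.651306,5.91
alpha-pinene,epsilon,trans,bare-hydroxylated,-465.652273,5.31
alpha-pinene,zeta,none,bare-hydroxylated,-465.660730,0.00
alpha-pinene,theta,none,bare-hydroxylated,-465.654240,4.07
alpha-pinene,iota,none,bare-hydroxylated,-465.646394,9
alpha-pinene,kappa,none,bare-hydroxylated,-465.646120,9.17
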