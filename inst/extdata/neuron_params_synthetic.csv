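pop,C_m,tau_m,E_L,V_th,V_r,t_ref,I_e_eglif,I_e_lif,k_adap,k_2,k_1,A_1,A_2,lambda_0,delta_V,f_target,cv_target
GoC,145,44,-62,-55,-75,2,10.41,27.39,0.005,0.1,0.2,20,50,500,1.6818,8,0.3
GrC,3,20,-74,-41,-84,1.5,0,0,0.001,0.05,0.2,2,1,500,1,0,NA
MLI,14.6,9.1,-68,-53,-78,1.6,23.94,24.07,0.003,0.1,0.2,5,10,500,0.1414,12,0.3
PC,620,47,-59,-43,-69,0.5,5514.36,1657.65,0.01,0.02,0.3,500,1000,500,4.1771,85,0.2
DCNp,80,40,-45,-36,-50,1.5,243.05,90.91,0.15,0.015,0.35,300,40,500,1.5,65,0.2
DCNi,56,56,-44,-38,-55,3,18.48,24.75,0.03,0.02,0.1,30,15,500,2.6505,25,0.3
IO,189,11,-45,-35,-45,1,93.15,100,0.3,0.05,0.1,100,100,500,1,1,NA
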