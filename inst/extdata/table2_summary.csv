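block,variable,label,mean,sd,n
absolute,stiffness_Nm_deg,LS,4.9,0.5,6
absolute,stiffness_Nm_deg,VFLS3,4.4,0.4,6
absolute,stiffness_Nm_deg,VFLS6,5.4,1.3,6
absolute,yield_Nm,LS,36.2,10.4,6
absolute,yield_Nm,VFLS3,37.3,6.9,6
absolute,yield_Nm,VFLS6,38.4,11.6,6
absolute,ultimate_Nm,LS,40.1,9.9,6
absolute,ultimate_Nm,VFLS3,44.3,10.0,6
absolute,ultimate_Nm,VFLS6,42.3,12.6,6
absolute,rotation_deg,LS,10.2,1.6,6
absolute,rotation_deg,VFLS3,11.1,2.3,6
absolute,rotation_deg,VFLS6,10.0,1.7,6
absolute,energy_Nm_deg,LS,253.2,85.2,6
absolute,energy_Nm_deg,VFLS3,285.7,127.4,6
absolute,energy_Nm_deg,VFLS6,265.2,93.1,6
normalized,stiffness_pct,LS,89.9,8.4,6
normalized,stiffness_pct,VFLS3,74.2,9.7,6
normalized,stiffness_pct,VFLS6,91.1,13.0,6
normalized,yield_pct,LS,63.8,25.9,6
normalized,yield_pct,VFLS3,71.7,24.7,6
normalized,yield_pct,VFLS6,64.2,27.8,6
normalized,ultimate_pct,LS,54.9,11.3,6
normalized,ultimate_pct,VFLS3,61.3,13.7,6
normalized,ultimate_pct,VFLS6,58.2,13.4,6
normalized,rotation_pct,LS,69.3,7.9,6
normalized,rotation_pct,VFLS3,79.5,13.9,6
normalized,rotation_pct,VFLS6,71.4,8.7,6
normalized,energy_pct,LS,43.0,10.8,6
normalized,energy_pct,VFLS3,54.7,24.3,6
normalized,energy_pct,VFLS6,47.2,16.2,6
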