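roi,variable,label,mean,sd,n
whole_bone,callus_volume_ccm,LS,8.9,1.6,6
whole_bone,callus_volume_ccm,VFLS3,12.5,3.5,6
whole_bone,callus_volume_ccm,VFLS6,17.1,5.1,6
whole_bone,callus_density_mgHA_ccm,LS,728,32,6
whole_bone,callus_density_mgHA_ccm,VFLS3,748,38,6
whole_bone,callus_density_mgHA_ccm,VFLS6,675,17,6
whole_bone,trans_callus_volume_ccm,LS,5.1,1.5,6
whole_bone,trans_callus_volume_ccm,VFLS3,6.2,2.3,6
whole_bone,trans_callus_volume_ccm,VFLS6,7.1,1.8,6
whole_bone,cis_callus_volume_ccm,LS,3.8,0.5,6
whole_bone,cis_callus_volume_ccm,VFLS3,6.2,1.7,6
whole_bone,cis_callus_volume_ccm,VFLS6,9.9,4.0,6
gap,callus_volume_ccm,LS,6.0,1.1,6
gap,callus_volume_ccm,VFLS3,6.8,1.3,6
gap,callus_volume_ccm,VFLS6,9.3,2.3,6
gap,callus_density_mgHA_ccm,LS,717,34,6
gap,callus_density_mgHA_ccm,VFLS3,730.8,44.9,6
gap,callus_density_mgHA_ccm,VFLS6,647.1,20.5,6
gap,trans_callus_volume_ccm,LS,3.7,1.0,6
gap,trans_callus_volume_ccm,VFLS3,3.8,1.1,6
gap,trans_callus_volume_ccm,VFLS6,4.4,1.3,6
gap,cis_callus_volume_ccm,LS,2.3,0.3,6
gap,cis_callus_volume_ccm,VFLS3,3.0,0.6,6
gap,cis_callus_volume_ccm,VFLS6,4.9,1.3,6
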