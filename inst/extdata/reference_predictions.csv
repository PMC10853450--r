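quantity,value,units,kind,description
st_all_30min,0.39,ug/mL,fluidsim_prediction,whole scala tympani volume-weighted mean Dex 30 min after intratympanic injection (porcine)
st1_30min,1.72,ug/mL,fluidsim_prediction,Dex 1 mm from the base 30 min after injection (porcine)
dsp_st_all_30min_no_hydrolysis,1.27,ug/mL,fluidsim_prediction,whole-ST DSP if none dephosphorylates
dsp_st1_30min_no_hydrolysis,5.84,ug/mL,fluidsim_prediction,DSP at 1 mm if none dephosphorylates
dex_st_all_30min_all_hydrolysis,1.65,ug/mL,fluidsim_prediction,whole-ST dephosphorylated DSP if all dephosphorylates
dex_st1_30min_all_hydrolysis,7.32,ug/mL,fluidsim_prediction,dephosphorylated DSP at 1 mm if all dephosphorylates
dex_perilymph_pooled,0.38,ug/mL,measured_mean,porcine perilymph Dex 30 min after Dex injection (20 uL pooled; mean of n=5)
dsp_total_perilymph,6.27,ug/mL,measured_mean,porcine perilymph DSP + Dex 30 min after DSP injection (mean of n=3)
diffusion_time_pig,8,days,fluidsim_prediction,total base-to-apex Dex diffusion time (porcine)
diffusion_time_human,6,days,fluidsim_prediction,total base-to-apex Dex diffusion time (human)
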