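key,value,note
spartina_area_1985_ha,514.53,"narrative 1985 value; the area table prints 214.53, only 514.53 is consistent with the stated 662.92% increase"
spartina_area_2017_ha,3925.46,
phragmites_area_1985_ha,5038.48,
phragmites_area_2017_ha,8751.37,"area-table value; narrative prints 8571.37, only 8751.37 is consistent with the stated 1.74x ratio"
suaeda_area_2017_simulated_ha,5662.05,"no-invasion counterfactual simulation"
suaeda_area_2017_observed_ha,992.46,
total_area_1985_ha,23830.43,
total_area_2017_ha,23830.60,
mudflat_area_2017_ha,8295.04,
phragmites_farthest_boundary_shift_m,3443,"seaward shift 1985-2017"
phragmites_farthest_boundary_span_yr,32,
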