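# photokin variant presets, v1
# Rate constants in 1e-3 s^-1; epsilon in 1e3 M^-1 cm^-1; amplitudes are unit-normalized.
# sw1_* describe the first on-to-off switching cycle (opposed = TRUE means the second
# exponential component is subtracted), sw2_* the second and later cycles (same sign).
# A missing sw k2 with ratio 0 denotes a mono-exponential cycle (no second component).
# Columns listed in `reconstructed` are not measured values: fatigue factors and
# per-cycle emission blue-shifts are illustrative defaults chosen for the generator.
name,pka,epsilon_1e3,phi,conv_k1_1e3,conv_k2_1e3,sw1_ratio,sw1_k1_1e3,sw1_k2_1e3,sw1_opposed,sw2_ratio,sw2_k1_1e3,sw2_k2_1e3,relax_k_1e3,fatigue,blue_shift_per_cycle_nm,reconstructed
mSAASoti,6.3,75.0,0.59,11,2,0.27,5.5,9.8,TRUE,0.26,7.8,24.7,22,1.0,-2,fatigue;blue_shift_per_cycle_nm
C21N,6.4,82.4,0.61,14,2,0.27,5.7,15.7,TRUE,0.76,5.3,13.7,9.5,1.0,-2,fatigue;blue_shift_per_cycle_nm
C105V,6.5,61.0,0.60,15,5,0.22,9.1,34.3,TRUE,2.06,7.1,17.9,17.9,1.0,-2,fatigue;blue_shift_per_cycle_nm
C71V,6.5,65.1,0.63,21,1,0.14,4.5,14.2,TRUE,0.40,5.1,15,15.5,1.0,-2,fatigue;blue_shift_per_cycle_nm
C117S,6.2,66.3,0.54,9,3,0.09,6.4,10.9,TRUE,0.24,6.4,15.6,9.7,1.0,-2,fatigue;blue_shift_per_cycle_nm
C21N_C71V,6.3,48.9,0.58,22,1,0.26,6.8,15.6,TRUE,0.20,7.4,22.8,12.5,1.0,-2,fatigue;blue_shift_per_cycle_nm
C175A,6.7,80.1,0.55,15,3,0,3.5,,FALSE,0.12,3.1,16,5.5,0.85,0,fatigue;blue_shift_per_cycle_nm
C21N_C175A,6.3,65.4,0.55,13,3,0,4.1,,FALSE,0.98,1.5,7.5,2.5,0.85,0,fatigue;blue_shift_per_cycle_nm
C21N_C71G_C175A,6.4,83.8,0.60,46,9,0,4.0,,FALSE,0,4.4,,4.5,0.85,0,fatigue;blue_shift_per_cycle_nm
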