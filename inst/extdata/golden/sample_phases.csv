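sample_id,phase_radians,phase_degrees,phase_hours,outlier_flag
S01,4.028998944,230.8446351,15.38964234,FALSE
S02,5.159446197,295.6144917,19.70763278,FALSE
S03,6.101605421,349.5962389,23.30641593,FALSE
S04,0.344819232,19.75668669,1.317112446,FALSE
S05,1.008538214,57.78498316,3.852332211,FALSE
S06,1.430821199,81.98001592,5.465334395,FALSE
S07,3.323787894,190.4390183,12.69593455,FALSE
S08,3.657726247,209.5722766,13.97148511,FALSE
S09,4.349753739,249.2225312,16.61483541,FALSE
S10,5.0382655,288.6713492,19.24475661,FALSE
S11,4.283778168,245.4424094,16.36282729,FALSE
S12,0.1863202618,10.67536464,0.7116909758,FALSE
S13,1.036039269,59.36067753,3.957378502,FALSE
S14,2.581969483,147.9359542,9.862396948,FALSE
S15,2.922190762,167.4291976,11.16194651,FALSE
S16,3.577718374,204.9881631,13.66587754,FALSE
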