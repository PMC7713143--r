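variable,current_control_pct,historical_control_pct
normalized_failure_torque,54.9,26.8
normalized_torsional_stiffness,89.9,58.89
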