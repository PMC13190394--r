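direction,lambda,p_value
CO2->MIGR,107.156,0.000
MIGR->CO2,104.003,0.000
HEXP->MIGR,90.565,0.001
MIGR->HEXP,92.942,0.001
HEXP->CO2,115.396,0.000
CO2->HEXP,117.682,0.000
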