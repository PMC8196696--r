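category,ap
bottle,0.939137
cap,0.89423
cup,0.831954
face,0.954092
hand,0.857066
mouth,0.777187
open_bottle,0.83886
open_mouth,0.947501
pill,0.827504
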