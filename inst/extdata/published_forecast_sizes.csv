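dataset,model,train_size,required_size_90pct
GDSC1,hGBDT,115863,649056
GDSC2,hGBDT,78423,598003
NCI-60,hGBDT,675000,18355942
CTRP,mNN,203650,322865
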