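((octopus:5000000,bimac:5000000):265000000,(squid:120000000,cuttlefish:120000000):150000000);
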