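{"anchor_left":"CCCCCACCACACTGAATCTC","anchor_right":"AGAGGGGAGGGGCCTAGGGA","inter_anchor_distance":32,"wt_reference":"CCTCACAGTTGCCAT","wt_offset_in_gap":8,"hamming_threshold":11,"allele_freq_min":0.002,"quant_window":30,"wt_amplicon":"TGACCTGAGCGTTAGCCATTGACGATTACCAGGCTTGACACCCCCACCACACTGAATCTCATCGGTACCCTCACAGTTGCCATTAGCCATTGAGAGGGGAGGGGCCTAGGGACATTGGACGTTAGGATCCAGTTCAGGATTACCGTTAGCAT","cut_offset":77,"hdr_reference":"GGAGCGCTAATGCAT","anchor_max_mismatch":0}
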