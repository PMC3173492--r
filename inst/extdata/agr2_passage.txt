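AGR2 has been implicated in cancer pathogenesis and has been found to be up-regulated in multiple human cancers, including breast, lung, and prostate. Our study has shown that AGR2 is higher in prostate cancer cells compared to non-malignant prostatic epithelial cells at the transcript and protein levels.
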