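>ir_reference_synthetic
MWSRWWPDEMQQCNSWWSDVDYWQSAQWCRESAVWGQLMPMYLSTMLGTFVWWNIPSYYN
EWYTCCTAPPPGCQGMSVPVYVYCDGGLEPCQKCGIRLCRWYKLELIWDIRWCTACPLQP
MLATDRANMEVKKNGYKPKDICTPQNWCAPDHVWPQNCRHYFNTVSSIWNCHCCETPAKC
HVHQGDKIDISCVSHITVRWMFMCMEAWSVFRQFWRFDMFRHIEIGAIGCAWNHKGWYRS
VRISKYYRIRIECGPRDQPDNVRQQADIEPYFTYQGMQTPHGWWMNEKQTATFNAHCCWK
QKRLKQMAADEWQKNAVADKKPRARSMAQIPGWPQLWPPEDEFVCQSHIINDAIMCGCWF
AEVDHFPIMKWWRTDFWPMILVCIIHVYVIQRGWDEESYPQWNSWFRQAVKCRTWNTWRE
YMGVHMNEYWAICMQDLQDGLNQGCMSCHGNTSMFVDHPIIDIFSCALGEKVSQIYWPLP
TLFKRSYLKTQAGHLTSALL
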