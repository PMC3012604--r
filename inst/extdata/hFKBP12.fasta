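>hFKBP12 Homo sapiens FK506-binding protein 1A (GenBank A35780; UniProt P62942)
MGVQVETISPGDGRTFPKRGQTCVVHYTGMLEDGKKFDSSRDRNKPFKFMLGKQEVIRGW
EEGVAQMSVGQRAKLTISPDYAYGATGHPGIIPPHATLVFDVELLKLE
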