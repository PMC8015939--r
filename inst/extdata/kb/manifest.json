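{
  "version": "fixture-1.0",
  "last_updated": "2026-01-15"
}
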