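[{"protein":"TFA","state":"D5","L":50,"events":[6.66666666666667,30]},{"protein":"TFB","state":"D5","L":50,"events":[13.8888888888889,34.4444444444444,47.7777777777778]},{"protein":"TFC","state":"D5","L":50,"events":[18.8888888888889,26.1111111111111]}]
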