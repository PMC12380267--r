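# Extension node for immune-regulation models: saturating inhibition.
# inhibit(x, ac, alpha) divides a production term x by (1 + alpha * ac),
# so the anti-inflammatory mediator ac suppresses x with strength alpha.

inhibit <- node(function(x, ac, alpha) x / (1 + alpha * ac))
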