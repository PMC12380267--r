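# Example extension file: trigonometric and power nodes.
# Each node() call defines a new expression-node operator; the function's
# parameter count fixes the node's number of input pins.

sin <- node(function(x) base::sin(x))

pow <- node(function(x, y) x ^ y, format = "$1 ^ $2")
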