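# Model intermediate representation (format_version "1.0")

A model file is a UTF-8 JSON object (conventional extension `.json`).
Serialization is deterministic: key order is fixed as below, node and link
order equals insertion order, and numbers carry 17 significant digits so
doubles round-trip exactly. Unknown `format_version` values are rejected.

```jsonc
{
  "format_version": "1.0",          // required
  "metadata": {                     // required
    "name":  "extended SIR",        // required
    "notes": ""                     // optional free text
  },
  "nodes": [                        // required; insertion order
    // one record per node; "id" and "kind" always required
    { "id": "n1", "kind": "term", "name": "S", "value": 195,
      "position": [40, 80] },      // position: optional opaque pair,
                                    // preserved on round-trip, never
                                    // interpreted
    { "id": "n12", "kind": "expression", "name": "infection",
      "operator": "multiply",       // add|subtract|multiply|divide, or the
      "arity": 3 },                 //   name of an extension function
    { "id": "n30", "kind": "assigner", "name": "S ode", "target": "n1" }
  ],
  "links": [                        // required; insertion order
    { "source": "n1", "destination": "n12", "destination_pin": 1 }
    // destination_pin is ZERO-based here (the R API is 1-based)
  ],
  "simulation": {                   // required
    "start_time": 0, "time_step": 1, "end_time": 1500,
    "x_label": "t", "y_label": "individuals",
    "rel_tol": 1e-06, "abs_tol": 1e-09,
    "method": "ode45"               // or "lsoda"
  },
  "extensions": [                   // optional; default []
    "inhibition.R"                  // paths relative to the model file's
  ]                                 //   directory (absolute allowed)
}
```

Structural rules enforced on load: unique node ids; every link endpoint
resolves to an existing node; link sources are terms or expressions and
destinations are expressions or assigners; at most one link per destination
pin; the link graph is acyclic; assigner targets are term nodes, at most one
assigner per term. Pins are implicit: a node's input-pin count derives from
its kind and arity.
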