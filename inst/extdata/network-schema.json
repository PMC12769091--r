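{
  "$comment": "Interchange format for templating-network description files (validated on load by templimits::load_network). All energies in k_BT; concentrations are dimensionless activities.",
  "type": "object",
  "required": ["nodes", "edges"],
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": {"type": "string", "description": "unique node label; the null complex is conventionally labelled Ø"},
          "kind": {"enum": ["null", "intermediate", "product"], "description": "exactly one node of kind 'null' per network"},
          "free_energy": {"type": ["number", "null"], "description": "optional normalised free energy G of the complex, k_BT (null complex fixed at 0)"}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["from", "to", "k_fwd", "k_rev"],
        "properties": {
          "from": {"type": "string"},
          "to": {"type": "string"},
          "k_fwd": {"type": "number", "exclusiveMinimum": 0, "description": "forward rate constant with chemostatted concentrations absorbed"},
          "k_rev": {"type": "number", "exclusiveMinimum": 0, "description": "reverse rate constant; every reaction is reversible"},
          "chem_work": {"type": ["number", "null"], "description": "optional chemostat bookkeeping: summed chemical-potential change of chemostatted species turned over by the reaction, k_BT"}
        }
      }
    },
    "meta": {
      "type": "object",
      "properties": {
        "M": {"type": "integer", "description": "product count (cross-checked against the nodes)"},
        "L": {"type": "number", "description": "polymer length metadata, L ~ ln M"},
        "G0": {"type": "number", "description": "standard free energy of product formation, k_BT"},
        "chemostats": {"type": "array", "description": "optional table of chemostatted species and normalised chemical potentials"}
      }
    }
  },
  "constraints": [
    "exactly one node has kind 'null'",
    "at least one node has kind 'product'",
    "no edge connects two product nodes",
    "no self-loop edges",
    "the undirected graph is connected: every node reachable from the null complex",
    "derived per edge: delta_g = -ln(k_fwd / k_rev) (local detailed balance)",
    "when free energies and chem_work are annotated: delta_g = G_to - G_from + chem_work within tolerance"
  ]
}
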