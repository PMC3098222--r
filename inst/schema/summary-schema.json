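{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "connectoclust pipeline summary",
  "type": "object",
  "required": ["seed", "n_nodes", "w", "best_q", "k", "cluster_sizes",
               "separated_pairs", "null_q_mean", "null_q_sd",
               "role_counts", "iqv_ntype", "nomenclature"],
  "properties": {
    "seed": {"type": "integer"},
    "n_nodes": {"type": "integer"},
    "w": {"type": "number"},
    "best_q": {"type": "number"},
    "k": {"type": "integer"},
    "cluster_sizes": {"type": "array", "items": {"type": "integer"}},
    "separated_pairs": {"type": "integer"},
    "null_q_mean": {"type": "number"},
    "null_q_sd": {"type": "number"},
    "role_counts": {"type": "object"},
    "iqv_ntype": {"type": "object"},
    "vi_top_mean": {"type": ["number", "null"]},
    "nomenclature": {"type": "object"},
    "vi_to_truth": {"type": "number"},
    "truth_k": {"type": "integer"}
  }
}
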