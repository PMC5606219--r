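{
  "$comment": "Structural schema of an epipanel session document (format_version 1.x). Enforced by the package's internal validator; listed here for human readers and external tooling.",
  "type": "object",
  "required": ["format_version", "genome_label", "settings", "panels", "filter_chain", "file_manifest"],
  "properties": {
    "format_version": {"type": "string", "pattern": "^1\\."},
    "genome_label": {"type": "string"},
    "settings": {
      "type": "object",
      "required": ["flank_up", "flank_down"],
      "properties": {
        "flank_up": {"type": "number", "minimum": 0},
        "flank_down": {"type": "number", "minimum": 0},
        "min_peak_score": {"type": "number"},
        "min_peak_size": {"type": "number"},
        "max_peak_size": {"type": ["number", "null"], "$comment": "null = unbounded"},
        "expr_scale_lo": {"type": ["number", "null"]},
        "expr_scale_hi": {"type": ["number", "null"]}
      }
    },
    "panels": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "flank_up", "flank_down", "gene_length", "tracks", "expression", "neighbors", "exons_rel", "show"],
        "properties": {
          "gene": {
            "type": "object",
            "required": ["gene_id", "chrom", "strand", "span_start", "span_end", "exons"],
            "properties": {
              "gene_id": {"type": "string"},
              "aliases": {"type": "array", "items": {"type": "string"}},
              "chrom": {"type": "string"},
              "strand": {"enum": ["+", "-"]},
              "span_start": {"type": "number"},
              "span_end": {"type": "number"},
              "exons": {"type": "array", "items": {"type": "array", "minItems": 2, "maxItems": 2}},
              "description": {"type": "string"}
            }
          },
          "flank_up": {"type": "number"},
          "flank_down": {"type": "number"},
          "gene_length": {"type": "number"},
          "tracks": {
            "type": "object",
            "$comment": "keyed '<cell_type>|<mark>'",
            "additionalProperties": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["rel_start", "rel_end", "score"],
                "properties": {
                  "rel_start": {"type": "number"},
                  "rel_end": {"type": "number"},
                  "score": {"type": "number"},
                  "signal_value": {"type": ["number", "null"]},
                  "name": {"type": "string"}
                }
              }
            }
          },
          "expression": {"type": "object", "additionalProperties": {"type": ["number", "null"]}},
          "neighbors": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["gene_id", "rel_start", "rel_end", "orientation"],
              "properties": {"orientation": {"enum": ["same", "opposite"]}}
            }
          },
          "exons_rel": {"type": "array", "items": {"type": "object", "required": ["rel_start", "rel_end"]}},
          "show": {"type": "boolean"}
        }
      }
    },
    "filter_chain": {"type": "array", "items": {"type": "object", "required": ["type"]}},
    "filter_trace": {"type": "array", "items": {"type": "integer"}},
    "file_manifest": {"type": "object", "additionalProperties": {"type": "array", "items": {"type": "string"}}}
  }
}
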