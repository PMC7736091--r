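## Structured error conditions. Every domain failure carries a condition
## class so callers (and the CLI) can branch without string matching.

.hmStop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    list(message = message, call = call),
    class = c(class, "hipmorph_error", "error", "condition")
  ))
}

degenerateGeometryError <- function(message)
  .hmStop("hipmorph_degenerate_geometry", message, sys.call(-1))

landmarkExtractionError <- function(message)
  .hmStop("hipmorph_landmark_extraction", message, sys.call(-1))

phantomConstructionError <- function(message)
  .hmStop("hipmorph_phantom_construction", message, sys.call(-1))

schemaError <- function(message)
  .hmStop("hipmorph_schema", message, sys.call(-1))

undefinedMetricError <- function(message)
  .hmStop("hipmorph_undefined_metric", message, sys.call(-1))

inputError <- function(message)
  .hmStop("hipmorph_input", message, sys.call(-1))
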