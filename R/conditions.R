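# Classed error conditions so callers (and the CLI) can distinguish
# validation problems from numerical failures.

stop_bigsm <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("bigsm_", class), "bigsm_error")))
}

# All validation-type condition classes map to CLI exit code 2; numerical
# failures map to 3.
bigsm_validation_classes <- c(
  "bigsm_invalid_config", "bigsm_degenerate_perturbation",
  "bigsm_degenerate_response", "bigsm_degenerate_normalization",
  "bigsm_dimension", "bigsm_parse", "bigsm_resolution",
  "bigsm_undefined_metric"
)
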