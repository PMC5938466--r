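# Classed conditions so callers (and the CLI) can react to specific failure
# modes rather than matching message strings.

abort_artirot <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "artirot_error")))
}

abort_validation <- function(msg) abort_artirot(msg, "artirot_validation")
abort_index      <- function(msg) abort_artirot(msg, "artirot_index")
abort_degenerate <- function(msg) abort_artirot(msg, "artirot_degenerate")
abort_reflection <- function(msg) abort_artirot(msg, "artirot_reflection")
abort_format     <- function(msg) abort_artirot(msg, "artirot_format")
abort_match      <- function(msg) abort_artirot(msg, "artirot_match")
abort_io         <- function(msg) abort_artirot(msg, "artirot_io")

warn_artirot <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "artirot_warning")))
}
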