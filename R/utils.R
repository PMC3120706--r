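#' @keywords internal
"_PACKAGE"

# Typed conditions ------------------------------------------------------------
#
# Every user-facing failure carries a condition class so callers (and the CLI)
# can react by kind rather than by matching message strings:
#   mirgram_parameter_error    invalid argument values
#   mirgram_io_error           missing/unwritable files
#   mirgram_format_error       malformed input content
#   mirgram_empty_input_error  structurally valid but empty input
#   mirgram_conflict_error     contradictory labels
#   mirgram_precondition_error dataset does not satisfy a protocol precondition
#   mirgram_training_error     classifier cannot be fitted
#   mirgram_compatibility_error model/data vocabulary mismatch
#   mirgram_undefined_metric   metric denominator is zero

mirgram_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "mirgram_error"), call = call))
}

abort_parameter <- function(message) mirgram_abort(message, "mirgram_parameter_error")
abort_io <- function(message) mirgram_abort(message, "mirgram_io_error")
abort_format <- function(message) mirgram_abort(message, "mirgram_format_error")
abort_empty <- function(message) mirgram_abort(message, "mirgram_empty_input_error")
abort_conflict <- function(message) mirgram_abort(message, "mirgram_conflict_error")
abort_precondition <- function(message) mirgram_abort(message, "mirgram_precondition_error")
abort_training <- function(message) mirgram_abort(message, "mirgram_training_error")
abort_compatibility <- function(message) mirgram_abort(message, "mirgram_compatibility_error")
abort_undefined_metric <- function(message) mirgram_abort(message, "mirgram_undefined_metric")

# Seeding ---------------------------------------------------------------------

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current RNG state" so that composite generators
# can derive all randomness from a single outer seed.
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_seed <- function(seed) {
  if (is.null(seed)) return(NULL)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_parameter("`seed` must be a single integer")
  }
  as.integer(seed)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_parameter(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1) {
    abort_parameter(sprintf("`%s` must be a single number in [0, 1)", name))
  }
  as.numeric(x)
}

# C-locale sort so A < C < G < U (and label order) is platform independent.
sort_c <- function(x) sort(x, method = "radix")
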