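#' Condition labels of the two-stressor factorial design
#'
#' The design crosses gravity (ST = standing 1G, RO = clinostat-rotated
#' simulated microgravity) with radiation (none, X = X-ray, C = carbon ion)
#' and post-irradiation harvest time (3 h, 24 h). Non-irradiated cultures
#' have no harvest time, giving 10 conditions in the canonical order used
#' throughout: ST, ST-X3, ST-X24, ST-C3, ST-C24, RO, RO-X3, RO-X24, RO-C3,
#' RO-C24.
#'
#' @return Character vector of the 10 condition labels.
#' @export
condition_labels <- function() {
  c("ST", "ST-X3", "ST-X24", "ST-C3", "ST-C24",
    "RO", "RO-X3", "RO-X24", "RO-C3", "RO-C24")
}

#' The 8 irradiated condition labels
#' @return Character vector (ST-X3 ... RO-C24, canonical order).
#' @export
irradiated_conditions <- function() {
  setdiff(condition_labels(), c("ST", "RO"))
}

#' Decompose a condition label into its factors
#' @param condition character vector of condition labels.
#' @return data.frame with columns condition, gravity, radiation, time.
#' @keywords internal
parse_condition <- function(condition) {
  ok <- condition %in% condition_labels()
  if (!all(ok)) {
    stop("unknown condition label(s): ", paste(condition[!ok], collapse = ", "))
  }
  gravity <- substr(condition, 1, 2)
  rest <- sub("^(ST|RO)-?", "", condition)
  radiation <- ifelse(rest == "", "none", substr(rest, 1, 1))
  time <- ifelse(rest == "", NA_integer_,
                 as.integer(sub("^[XC]", "", rest)))
  data.frame(condition = condition, gravity = gravity,
             radiation = radiation, time = time,
             stringsAsFactors = FALSE)
}

#' Build the per-sample design table
#'
#' Expands a replicates map (condition label -> replicate count) into one
#' row per sample. Sample ids are `<condition>_r<replicate>`.
#'
#' @param replicates named integer vector covering exactly the 10 conditions
#'   of [condition_labels()]. Default: 6 replicates for the non-irradiated
#'   ST and RO cultures, 3 for each irradiated condition (36 samples).
#' @return data.frame with columns sample_id, gravity, radiation, time,
#'   replicate, condition.
#' @export
build_design <- function(replicates = default_replicates()) {
  labs <- condition_labels()
  if (!setequal(names(replicates), labs)) {
    stop("replicates map must cover exactly the 10 design conditions")
  }
  replicates <- replicates[labs]
  if (any(replicates < 1)) stop("every condition needs >= 1 replicate")
  cond <- rep(labs, times = replicates)
  repl <- unlist(lapply(replicates, seq_len), use.names = FALSE)
  out <- parse_condition(cond)
  out$replicate <- repl
  out$sample_id <- paste0(out$condition, "_r", repl)
  out[, c("sample_id", "gravity", "radiation", "time", "replicate", "condition")]
}

#' @rdname build_design
#' @export
default_replicates <- function() {
  stats::setNames(c(6L, rep(3L, 4L), 6L, rep(3L, 4L)), condition_labels())
}

#' Sample ids belonging to given conditions
#' @param design design data.frame from [build_design()] or [read_design()].
#' @param conditions condition labels to select.
#' @keywords internal
samples_of <- function(design, conditions) {
  design$sample_id[design$condition %in% conditions]
}
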