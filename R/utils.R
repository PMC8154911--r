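# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup bind_cols
#'   left_join full_join bind_rows across all_of n
#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed seed without disturbing the caller's RNG;
# a NULL seed uses the ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive `n` child seeds from one parent seed so that nested stochastic stages
# are independently reproducible. NULL parent -> NULL children (ambient RNG).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(vector("list", n))
  }
  as.list(with_seed_if(seed, sample.int(2147483646L, n)))
}

stop_config <- function(msg, ...) {
  abort(msg, class = "geothermflora_invalid_config", ...)
}

stop_parse <- function(msg, ...) {
  abort(msg, class = "geothermflora_parse_error", ...)
}

stop_lookup <- function(msg, ...) {
  abort(msg, class = "geothermflora_lookup_error", ...)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop_config(sprintf("`%s` must be a single integer >= %d, got %s.",
                        name, min, deparse(x)))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_config(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  as.numeric(x)
}

# Decode linear indices of unordered pairs (1,2),(1,3),...,(1,n),(2,3),...
# into (i, j) with i < j. Vectorised over `m`.
pair_from_index <- function(m, n) {
  cum <- cumsum(n - seq_len(n - 1L))
  i <- findInterval(m - 1L, c(0L, cum)) # block = smaller member
  offset <- m - c(0L, cum)[i]
  cbind(i = i, j = i + offset)
}
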