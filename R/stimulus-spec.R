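#' Target stimulus specification
#'
#' The arithmetic skeleton of the concatenated-SAM-tone target.  All component
#' frequencies are integer multiples of the token presentation rate
#' (`base_rate_hz`), which is what guarantees that every token completes an
#' integer number of carrier and AM periods and can be concatenated without
#' discontinuities.
#'
#' @param base_rate_hz token presentation rate in Hz (default 6.8; one token
#'   lasts `1/base_rate_hz` s).
#' @param carrier_multiple integer carrier multiple of the base rate
#'   (default 76, i.e. a 516.8 Hz carrier).
#' @param am_multiples ordered distinct positive integers giving the AM rates
#'   as multiples of the base rate (default `c(4, 6, 8, 10, 12)`, true rates
#'   27.2/40.8/54.4/68/81.6 Hz, nominal 27/41/54/68/82 Hz).
#' @param sample_rate_hz audio sampling rate (default 44100).
#' @param mod_depth modulation depth in (0, 1] (default 1).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(base_rate_hz = 6.8,
                          carrier_multiple = 76L,
                          am_multiples = c(4L, 6L, 8L, 10L, 12L),
                          sample_rate_hz = 44100,
                          mod_depth = 1) {
  if (base_rate_hz <= 0) abort("base_rate_hz must be positive")
  if (carrier_multiple != round(carrier_multiple) || carrier_multiple < 1) {
    abort("carrier_multiple must be a positive integer")
  }
  if (any(am_multiples != round(am_multiples)) || any(am_multiples < 1)) {
    abort("am_multiples must be positive integers")
  }
  if (anyDuplicated(am_multiples)) abort("am_multiples must be distinct")
  if (mod_depth <= 0 || mod_depth > 1) abort("mod_depth must be in (0, 1]")
  structure(
    list(
      base_rate_hz = base_rate_hz,
      carrier_multiple = as.integer(carrier_multiple),
      am_multiples = as.integer(am_multiples),
      tokens_per_cycle = length(am_multiples),
      sample_rate_hz = sample_rate_hz,
      mod_depth = mod_depth
    ),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<stimulus_spec: base %g Hz, carrier %g Hz (x%d), AM rates %s Hz,\n",
      "  %d tokens/cycle, fs %g Hz, depth %g>\n"
    ),
    x$base_rate_hz, x$carrier_multiple * x$base_rate_hz, x$carrier_multiple,
    paste(round(x$am_multiples * x$base_rate_hz, 1), collapse = "/"),
    x$tokens_per_cycle, x$sample_rate_hz, x$mod_depth
  ))
  invisible(x)
}

#' True and nominal AM rates of a spec
#' @param spec a [stimulus_spec()].
#' @return tibble with `am_index`, `am_multiple`, `rate_hz`, `nominal_hz`.
#' @export
am_rates <- function(spec) {
  tibble(
    am_index = seq_along(spec$am_multiples),
    am_multiple = spec$am_multiples,
    rate_hz = spec$am_multiples * spec$base_rate_hz,
    nominal_hz = round(spec$am_multiples * spec$base_rate_hz)
  )
}

#' Read a stimulus specification from a YAML config
#'
#' The config must carry an explicit `seed` field alongside the
#' [stimulus_spec()] fields; the seed is returned in the `seed` attribute so
#' callers cannot silently run unseeded.
#'
#' @param path YAML file path.
#' @return a `stimulus_spec` with attribute `seed`.
#' @export
read_stimulus_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("config must set an rng seed")
  fields <- intersect(
    names(cfg),
    c("base_rate_hz", "carrier_multiple", "am_multiples", "sample_rate_hz",
      "mod_depth")
  )
  spec <- do.call(stimulus_spec, cfg[fields])
  attr(spec, "seed") <- as.integer(cfg$seed)
  spec
}

all_permutations <- function(n) {
  # lexicographic permutations of 1..n
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Enumerate all token orderings
#'
#' All permutations of the AM indices, in lexicographic order.  With the
#' default five tokens this is the full set of 120 pattern stimuli.
#'
#' @param spec a [stimulus_spec()].
#' @return integer matrix, one permutation per row.
#' @export
enumerate_patterns <- function(spec) {
  all_permutations(spec$tokens_per_cycle)
}

#' Draw one pseudo-random cycle
#'
#' Uniformly samples a permutation of the AM indices whose first token is not
#' `prev_last`, so a random segment never repeats the final SAM tone of the
#' previous cycle as the first tone of the next.  Uses the current RNG state;
#' seed with [set.seed()] for reproducibility.
#'
#' @param spec a [stimulus_spec()].
#' @param prev_last AM index of the last token of the previous cycle, or
#'   `NULL` for the first cycle.
#' @return integer vector: one permutation of `1:tokens_per_cycle`.
#' @export
draw_random_cycle <- function(spec, prev_last = NULL) {
  n <- spec$tokens_per_cycle
  idx <- seq_len(n)
  allowed_first <- if (is.null(prev_last)) idx else setdiff(idx, prev_last)
  # uniform over the allowed permutation set: every allowed first element
  # heads the same number ((n-1)!) of permutations
  first <- allowed_first[sample.int(length(allowed_first), 1L)]
  rest <- setdiff(idx, first)
  c(first, rest[sample.int(length(rest))])
}

#' Plan the cycle structure of one target stimulus
#'
#' Builds the per-cycle token orderings for a `random-random` or
#' `random-pattern` stimulus.  In a random-pattern plan the cycles at and
#' after `transition_cycle` all repeat `pattern` verbatim; before it (and in
#' random-random plans throughout) cycles are drawn with
#' [draw_random_cycle()].  Stimulus polarity alternates between cycles,
#' starting positive.
#'
#' @param spec a [stimulus_spec()].
#' @param n_cycles total number of cycles (4 for the speeded task, 12 for the
#'   EEG task).
#' @param context `"random-random"` or `"random-pattern"`.
#' @param transition_cycle cycle index (1-based) where the repeating pattern
#'   begins; default 5 (four random cycles then the pattern).  Ignored for
#'   random-random.
#' @param pattern permutation to repeat (random-pattern only); drawn randomly
#'   if `NULL`.
#' @return an object of class `cycle_plan`.
#' @export
cycle_plan <- function(spec, n_cycles,
                       context = c("random-random", "random-pattern"),
                       transition_cycle = 5L, pattern = NULL) {
  context <- match.arg(context)
  if (n_cycles < 1) abort("n_cycles must be >= 1")
  cycles <- vector("list", n_cycles)
  if (context == "random-pattern") {
    if (transition_cycle < 2 || transition_cycle > n_cycles) {
      abort("transition_cycle must lie inside the plan")
    }
    if (is.null(pattern)) pattern <- draw_random_cycle(spec)
    validate_permutation(pattern, spec$tokens_per_cycle)
  }
  prev_last <- NULL
  for (k in seq_len(n_cycles)) {
    if (context == "random-pattern" && k >= transition_cycle) {
      cycles[[k]] <- pattern
    } else {
      cyc <- draw_random_cycle(spec, prev_last)
      if (context == "random-pattern" && k == transition_cycle - 1L) {
        # the cycle feeding into the pattern must not end on the pattern's
        # first token (no-repeat rule at the transition)
        while (cyc[spec$tokens_per_cycle] == pattern[1]) {
          cyc <- draw_random_cycle(spec, prev_last)
        }
      }
      cycles[[k]] <- cyc
    }
    prev_last <- cycles[[k]][spec$tokens_per_cycle]
  }
  structure(
    list(
      cycles = cycles,
      context = context,
      transition_cycle = if (context == "random-pattern") as.integer(transition_cycle) else NA_integer_,
      polarity = rep_len(c(1L, -1L), n_cycles),
      spec = spec
    ),
    class = "cycle_plan"
  )
}

validate_permutation <- function(p, n) {
  if (!setequal(p, seq_len(n)) || length(p) != n) {
    abort("not a permutation of the AM indices")
  }
  invisible(p)
}

validate_cycle_plan <- function(plan) {
  if (!inherits(plan, "cycle_plan")) abort("not a cycle_plan")
  n <- plan$spec$tokens_per_cycle
  for (k in seq_along(plan$cycles)) {
    validate_permutation(plan$cycles[[k]], n)
    if (k > 1 && plan$cycles[[k]][1] == plan$cycles[[k - 1]][n]) {
      abort("cycle repeats the previous cycle's last token first")
    }
  }
  if (!all(plan$polarity == rep_len(c(1L, -1L), length(plan$cycles)))) {
    abort("polarity must strictly alternate starting +1")
  }
  invisible(plan)
}

#' @export
print.cycle_plan <- function(x, ...) {
  cat(sprintf(
    "<cycle_plan: %d cycles, %s%s>\n",
    length(x$cycles), x$context,
    if (!is.na(x$transition_cycle)) {
      sprintf(", pattern from cycle %d", x$transition_cycle)
    } else ""
  ))
  invisible(x)
}
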