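# Independent oracles and small fixtures used across the suite.

# A tiny 4-analyte panel with explicit retention times.
tinyPanel <- function() {
  buildPanel(
    mix_codes = c("C14:0", "C16:0", "C18:0", "C18:1n9c"),
    reference_code = "C16:0",
    expected_rt = c("C14:0" = 5, "C16:0" = 10, "C18:0" = 15,
                    "C18:1n9c" = 16)
  )
}

# Exhaustive best matching of expected RTs to peaks: maximise the number of
# matches, then minimise total |dRT|. Recursion over analytes; each analyte
# may take any unused peak within tolerance or stay unmatched. Independent
# of the package's dynamic program.
bruteMatch <- function(expected, observed, tol) {
  n <- length(expected)
  best <- list(matches = -1L, cost = Inf)
  recurse <- function(i, used, matches, cost) {
    if (i > n) {
      if (matches > best$matches ||
          (matches == best$matches && cost < best$cost)) {
        best <<- list(matches = matches, cost = cost)
      }
      return(invisible())
    }
    recurse(i + 1L, used, matches, cost)   # leave analyte i unmatched
    for (j in seq_along(observed)) {
      if (!used[j] && abs(expected[i] - observed[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, matches + 1L, cost + abs(expected[i] - observed[j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(observed)), 0L, 0)
  best
}

# Matched count and total |dRT| achieved by the package's assignment.
assignmentScore <- function(expected, observed, tol) {
  idx <- fameqc:::.matchLadder(expected, observed, tol)
  hit <- !is.na(idx)
  list(matches = sum(hit), cost = sum(abs(expected[hit] - observed[idx[hit]])))
}

# Expand a (n, mean, sd) summary into raw values matching it exactly.
expandSummary <- function(n, mean, sd) {
  x <- seq_len(n)
  z <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * z
}
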