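# Shared fixtures and independent oracles.

# random measurement series: irregular integer days, values around the
# target bound so all four interval classes and cluster shapes occur
random_series <- function(id = "P1", cm = "SBP", n = NULL,
                          bound_low = NA, bound_high = 140) {
  if (is.null(n)) n <- sample(1:15, 1)
  day <- sort(sample(0:2000, n))
  center <- if (!is.na(bound_high)) bound_high else bound_low
  value <- round(rnorm(n, center, 12), 1)
  cm_series(id, cm, day, value)
}

random_target <- function(cm = "SBP") {
  kind <- sample(c("high", "low", "both"), 1)
  switch(kind,
         high = target_spec(cm, high = 140),
         low = target_spec(cm, low = 140),
         both = target_spec(cm, low = 130, high = 150))
}

# fold a series through the incremental running summary
incremental_derive <- function(series, target, mode = "full") {
  rs <- new_running_summary(target)
  for (i in seq_along(series$day))
    rs <- update_summary(rs, series$day[i], series$value[i])
  finalize_summary(rs, mode)
}

expect_parameters_equal <- function(a, b, tol = 1e-9) {
  int_fields <- c("FUDaysNotAtGoal", "NumNotAtGoal", "TimeNotAtGoal",
                  "CtNotAtGoal", "MaxClustDays", "NumClust")
  for (p in parameter_names()) {
    av <- a[[p]]; bv <- b[[p]]
    if (is.na(av) || is.na(bv)) {
      expect_true(is.na(av) && is.na(bv),
                  label = sprintf("%s missingness agrees (%s vs %s)", p,
                                  format(av), format(bv)))
    } else if (p %in% int_fields) {
      expect_identical(as.numeric(av), as.numeric(bv), label = p)
    } else {
      expect_equal(as.numeric(av), as.numeric(bv), tolerance = tol,
                   label = p)
    }
  }
}

# O(n^2) pairwise concordance oracle for the AUROC (ties count one half)
auroc_pairwise_oracle <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# the worked 4-reading series used throughout the documentation
worked_series <- function() {
  cm_series("P1", "SBP", c(0, 10, 20, 30), c(130, 150, 160, 135))
}
worked_target <- function() target_spec("SBP", high = 140)

extdata <- function(f) system.file("extdata", f, package = "longlabs")
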