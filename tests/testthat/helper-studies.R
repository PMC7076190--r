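# Study runs shared between acceptance-style tests; computed once per test
# session on first use.
.study_memo <- new.env(parent = emptyenv())

memo_study <- function(key, expr) {
  if (!exists(key, envir = .study_memo)) {
    assign(key, force(expr), envir = .study_memo)
  }
  get(key, envir = .study_memo)
}

study1_reduced <- function() {
  memo_study("s1", run_study(1, seed = 1, noise = c("LNL", "HNL"), N = 1000))
}

study4_reduced <- function() {
  memo_study("s4", run_study(4, seed = 1, n_reps = 1))
}

study3_reduced <- function() {
  memo_study("s3", run_study(3, seed = 1, n_reps = 3))
}
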