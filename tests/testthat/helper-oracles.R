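# Independent brute-force oracle for sliding-window n-gram counting.
# Deliberately naive (character loop, per-window membership test) so it
# shares no code with the package implementation.
oracle_count_ngrams <- function(bases, n) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  counts <- list()
  total <- 0L
  if (L >= n) {
    for (s in 1:(L - n + 1L)) {
      win <- ch[s:(s + n - 1L)]
      if (all(win %in% c("A", "C", "G", "U"))) {
        g <- paste(win, collapse = "")
        counts[[g]] <- (if (is.null(counts[[g]])) 0L else counts[[g]]) + 1L
        total <- total + 1L
      }
    }
  }
  list(counts = counts, total = total)
}

# Random test sequence with a fraction of injected non-AUGU noise letters.
random_seq <- function(len, noise_frac = 0) {
  alphabet <- c("A", "C", "G", "U")
  noise <- c("N", "R", "Y", "S", "W", "K")
  ch <- sample(alphabet, len, replace = TRUE)
  if (noise_frac > 0 && len > 0) {
    hit <- runif(len) < noise_frac
    ch[hit] <- sample(noise, sum(hit), replace = TRUE)
  }
  paste(ch, collapse = "")
}

# Two well-separated 2-D point clouds for classifier unit tests.
separable_clouds <- function(n_per = 20L, seed = 1L) {
  withr::with_seed(seed, {
    X <- rbind(
      cbind(rnorm(n_per, 0, 0.05), rnorm(n_per, 1, 0.05)),
      cbind(rnorm(n_per, 1, 0.05), rnorm(n_per, 0, 0.05))
    )
    list(X = X, y = rep(c("a", "b"), each = n_per))
  })
}

tiny_fasta <- function(text) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(text, f)
  f
}
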