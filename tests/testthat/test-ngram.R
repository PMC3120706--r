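test_that("vocabulary dimensions and concentrations follow 4^n over the selected types", {
  v <- build_vocabulary(1:4)
  expect_identical(v$length, 340L)
  expect_equal(v$concentrations[["3"]], 64 / 340)
  expect_equal(sum(v$concentrations), 1, tolerance = 1e-12)
  # layout: tetragrams first, unigrams last; lexicographic within a type
  expect_identical(v$grams[1:2], c("AAAA", "AAAC"))
  expect_identical(v$grams[337:340], c("A", "C", "G", "U"))
  expect_identical(v$grams[v$blocks[["2"]]][1:5], c("AA", "AC", "AG", "AU", "CA"))

  v3 <- build_vocabulary(3)
  expect_identical(v3$length, 64L)
  expect_equal(v3$concentrations[["3"]], 1)

  v123 <- build_vocabulary(1:3)
  expect_identical(v123$length, 84L)
  expect_equal(v123$concentrations[["3"]], 64 / 84)

  expect_error(build_vocabulary(integer(0)), class = "mirgram_parameter_error")
  expect_error(build_vocabulary(c(1, 9)), class = "mirgram_parameter_error")
})

test_that("sliding-window counts overlap, skip noise windows, and handle short input", {
  v <- build_vocabulary(1:4)
  nc <- count_ngrams("AAAA", build_vocabulary(3))
  expect_identical(nc$counts[["3"]], c(AAA = 2L))
  expect_identical(unname(nc$totals[["3"]]), 2L)

  nc2 <- count_ngrams("ACNGU", build_vocabulary(2))
  expect_identical(nc2$counts[["2"]], c(AC = 1L, GU = 1L))
  expect_identical(unname(nc2$totals[["2"]]), 2L)

  nc3 <- count_ngrams("ACGUACGU", v)
  expect_identical(unname(nc3$totals[c("1", "2", "3", "4")]),
                   c(8L, 7L, 6L, 5L))

  # shorter than n: zero total, no error
  nc4 <- count_ngrams("AC", v)
  expect_identical(unname(nc4$totals[["4"]]), 0L)
})

test_that("counting agrees with the brute-force window enumerator on random noisy sequences", {
  v <- build_vocabulary(1:4)
  withr::with_seed(101, {
    for (rep in 1:200) {
      s <- random_seq(sample(1:200, 1), noise_frac = 0.05)
      nc <- count_ngrams(s, v)
      for (n in v$types) {
        ora <- oracle_count_ngrams(s, n)
        expect_identical(unname(nc$totals[[as.character(n)]]), ora$total)
        got <- nc$counts[[as.character(n)]]
        ref <- unlist(ora$counts)
        if (is.null(ref)) ref <- stats::setNames(integer(0), character(0))
        got <- got[order(names(got))]
        ref <- ref[order(names(ref))]
        expect_identical(unname(got), unname(ref))
        expect_identical(as.character(names(got)), as.character(names(ref)))
      }
    }
  })
})

test_that("feature values follow C_i * t_j / T_i with an all-zero block when T_i = 0", {
  v <- build_vocabulary(1:4)
  x <- featurize("AAAA", v)
  nz <- x[x > 0]
  expect_identical(names(nz), c("AAAA", "AAA", "AA", "A"))
  expect_equal(unname(nz), c(256, 64, 16, 4) / 340)
  expect_equal(sum(x), 1, tolerance = 1e-12)

  # too short for tetragrams: that block is zero and the sum drops to 84/340
  x2 <- featurize("ACG", v)
  expect_true(all(x2[v$blocks[["4"]]] == 0))
  expect_equal(sum(x2), 84 / 340, tolerance = 1e-12)
})

test_that("feature vectors of valid sequences are non-negative and sum to 1", {
  v <- build_vocabulary(1:4)
  withr::with_seed(33, {
    for (rep in 1:50) {
      x <- featurize(random_seq(sample(10:150, 1)), v)
      expect_true(all(x >= 0))
      expect_equal(sum(x), 1, tolerance = 1e-9)
    }
  })
})

test_that("featurization is invariant to case and to T-vs-U spelling", {
  v <- build_vocabulary(1:4)
  s <- "ACGUUGCAUGGACUUA"
  expect_identical(featurize(normalize_bases(tolower(s)), v), featurize(s, v))
  expect_identical(featurize(normalize_bases(chartr("U", "T", s)), v),
                   featurize(s, v))
})

test_that("a single-base change perturbs at most 10 windows and the vector boundedly", {
  v <- build_vocabulary(1:4)
  withr::with_seed(44, {
    for (rep in 1:10) {
      s <- random_seq(100)
      pos <- sample(100, 1)
      ch <- strsplit(s, "")[[1]]
      ch[pos] <- sample(setdiff(c("A", "C", "G", "U"), ch[pos]), 1)
      s2 <- paste(ch, collapse = "")
      for (n in 1:4) {
        a <- oracle_count_ngrams(s, n)
        b <- oracle_count_ngrams(s2, n)
        grams <- union(names(a$counts), names(b$counts))
        changed <- sum(vapply(grams, function(g) {
          ca <- if (is.null(a$counts[[g]])) 0L else a$counts[[g]]
          cb <- if (is.null(b$counts[[g]])) 0L else b$counts[[g]]
          ca != cb
        }, logical(1)))
        # a window of size n covering the position can change at most n grams
        # on each side (old gram decremented, new gram incremented)
        expect_lte(changed, 2 * n)
      }
      # L1 feature change: each type block moves at most C_i * 2n / T_i
      d <- sum(abs(featurize(s, v) - featurize(s2, v)))
      bound <- sum(vapply(1:4, function(n)
        v$concentrations[[as.character(n)]] * 2 * n / (100 - n + 1),
        numeric(1)))
      expect_lte(d, bound + 1e-12)
    }
  })
})

test_that("dataset featurization aligns rows with records deterministically", {
  ds <- mir_seqs(c("a", "b", "a2"), c("ACGUACGUAA", "UUGGCCAAUU", "ACGUACGUAA"),
                 family = c("f1", "f2", "f1"))
  v <- build_vocabulary(1:2)
  fd <- featurize_dataset(ds, v)
  expect_identical(dim(fd$X), c(3L, 20L))
  expect_identical(rownames(fd$X), ds$id)
  expect_identical(fd$y, ds$family)
  # identical sequences give identical rows
  expect_identical(fd$X[1, ], fd$X[3, ])
  # permuting input permutes rows
  fd_perm <- featurize_dataset(ds[c(2, 1, 3), ], v)
  expect_identical(fd_perm$X[2, ], fd$X[1, ])
})

test_that("family centers, distances and variances obey their closed forms", {
  v1 <- c(1, 0, 0)
  v2 <- c(0, 1, 0)
  expect_identical(family_center(rbind(v1)), c(1, 0, 0))
  expect_equal(family_center(list(v1, v2)), c(0.5, 0.5, 0))
  expect_equal(center_distance(v1, v1), 0)
  expect_equal(center_distance(v1, v2), sqrt(2))
  expect_equal(center_distance(v1, v2), center_distance(v2, v1))
  expect_error(center_distance(v1, c(1, 2)), class = "mirgram_parameter_error")

  centers <- rbind(c(0, 5), c(2, 5))
  expect_equal(feature_variance_across_families(centers), c(1, 0))
  expect_equal(feature_variance_across_families(centers * 3), c(9, 0))
  expect_error(feature_variance_across_families(rbind(v1)),
               class = "mirgram_parameter_error")
  # mean of unit-sum vectors sums to 1
  X <- featurize_dataset(generate_families(n_families = 1, seed = 9),
                         build_vocabulary(1:3))$X
  expect_equal(sum(family_center(X)), 1, tolerance = 1e-9)
})

test_that("counting cross-checks against an established k-mer counter", {
  # independent route: DNA-spell the sequence and count k-mers with
  # Biostrings, which also drops windows containing ambiguity letters
  v <- build_vocabulary(1:4)
  withr::with_seed(55, {
    for (rep in 1:10) {
      s <- random_seq(sample(30:120, 1), noise_frac = 0.1)
      dna <- Biostrings::DNAString(chartr("U", "T", s))
      for (n in 1:4) {
        ref <- Biostrings::oligonucleotideFrequency(dna, n)
        names(ref) <- chartr("T", "U", names(ref))
        nc <- count_ngrams(s, v)$counts[[as.character(n)]]
        full <- setNames(integer(length(ref)), names(ref))
        full[names(nc)] <- nc
        expect_identical(unname(full[names(ref)]), unname(as.integer(ref)))
      }
    }
  })
})

test_that("feature matrices export to CSV and SVM-light faithfully", {
  ds <- generate_families(n_families = 2, members_per_family = 3, seed = 2)
  v <- build_vocabulary(1:2)
  fd <- featurize_dataset(ds, v)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(fd$X, csv)
  back <- utils::read.csv(csv, row.names = 1, check.names = FALSE)
  expect_identical(colnames(back), v$grams)
  expect_equal(as.matrix(back), fd$X, tolerance = 1e-12)

  svml <- withr::local_tempfile(fileext = ".svm")
  write_svmlight(fd$X, fd$y, svml)
  lines <- readLines(svml)
  expect_length(lines, nrow(fd$X))
  first <- strsplit(lines[1], " ")[[1]]
  expect_identical(first[1], "1")  # fam_001 is label code 1
  pairs <- do.call(rbind, strsplit(first[-1], ":", fixed = TRUE))
  idx <- as.integer(pairs[, 1])
  expect_true(all(idx >= 1 & idx <= v$length))
  expect_equal(as.numeric(pairs[, 2]), unname(fd$X[1, idx]), tolerance = 1e-9)
})
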