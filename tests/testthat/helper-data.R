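# shared fixtures built in code

# write a small wide-layout volatile CSV and return its path
tmp_wide_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "wide.csv")
  writeLines(c("compound,S1,S2",
               "limonene,10,20",
               "hexanal,0.5,0.1",
               "acetoin,3,0"), path)
  path
}

tmp_long_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "long.csv")
  writeLines(c("compound,sample,value",
               "limonene,S1,10", "limonene,S2,20",
               "hexanal,S1,0.5", "hexanal,S2,0.1",
               "acetoin,S1,3", "acetoin,S2,0"), path)
  path
}

tmp_threshold_csv <- function(rows,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "thresholds.csv")
  writeLines(c("compound,opt,series_ids,descriptor", rows), path)
  path
}

# seeded random matrix
rmat <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# two well-separated Gaussian classes in 2D (centers +-5 sigma)
separated_classes <- function(n_per = 10, seed = 7) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2, mean = 5), ncol = 2),
             matrix(rnorm(n_per * 2, mean = -5), ncol = 2))
  list(X = X, labels = rep(c("A", "B"), each = n_per))
}
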