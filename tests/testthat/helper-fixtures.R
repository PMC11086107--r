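# Shared fixtures and independent oracles used across the suite.

# artifact-free generator settings for ground-truth checks
clean_synth_config <- function(...) {
  synth_config(noise_sd = 0, drift_amp = 0, spike_rate = 0, abp_noise_sd = 0,
               ...)
}

# a small preprocessed segment table built from synthetic records
make_segments <- function(n_records = 4, duration_s = 120, window_len = 1024,
                          seed = 42, ...) {
  ds <- synth_dataset(synth_config(n_records = n_records,
                                   duration_s = duration_s, seed = seed, ...))
  suppressMessages(preprocess_records(
    ds$records,
    preprocess_config(min_duration_s = 60, window_len = window_len,
                      seed = seed)
  ))
}

# Independent literal transcription of the GRU gate equations, scalar loops
# only (no reuse of package internals). params as in gru_step().
oracle_gru_step <- function(x_t, h_prev, params) {
  H <- length(h_prev)
  u <- c(h_prev, x_t)
  r <- numeric(H); z <- numeric(H); htil <- numeric(H); h <- numeric(H)
  for (i in seq_len(H)) {
    r[i] <- 1 / (1 + exp(-(sum(params$W_r[i, ] * u) + params$b_r[i])))
    z[i] <- 1 / (1 + exp(-(sum(params$W_z[i, ] * u) + params$b_z[i])))
  }
  u2 <- c(r * h_prev, x_t)
  for (i in seq_len(H)) {
    htil[i] <- tanh(sum(params$W[i, ] * u2) + params$b[i])
    h[i] <- (1 - z[i]) * h_prev[i] + z[i] * htil[i]
  }
  h
}

# Independent composition squeeze -> GRU scan -> projection -> sigmoid.
oracle_se_gru_weights <- function(x, params) {
  C <- nrow(x)
  z <- apply(x, 1, mean)
  H <- nrow(params$W_r)
  h <- numeric(H)
  s <- numeric(C)
  for (t in seq_len(C)) {
    h <- oracle_gru_step(z[t], h, params)
    s[t] <- 1 / (1 + exp(-(sum(params$w_p * h) + params$b_p)))
  }
  s
}

# finite-difference gradient check of one module on input gradient and params
fd_check_module <- function(make_module, x, eps = 1e-6, tol = 1e-4,
                            train = TRUE) {
  m <- make_module()
  y <- m$forward(x, train)
  set.seed(99)
  dy <- array(stats::rnorm(length(y)), dim(y))
  loss <- function(yy) sum(yy * dy)
  zero_grads_leaf(m)
  dx <- m$backward(dy)
  # input gradient
  worst <- 0
  idx <- sample(length(x), min(6, length(x)))
  for (ii in idx) {
    xp <- x; xp[ii] <- xp[ii] + eps
    xm <- x; xm[ii] <- xm[ii] - eps
    num <- (loss(m$forward(xp, train)) - loss(m$forward(xm, train))) / (2 * eps)
    worst <- max(worst, abs(num - dx[ii]))
  }
  # parameter gradients (grads were accumulated by the backward call above)
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (ii in idx) {
      p0 <- m$params[[nm]][ii]
      m$params[[nm]][ii] <- p0 + eps
      lp <- loss(m$forward(x, train))
      m$params[[nm]][ii] <- p0 - eps
      lm <- loss(m$forward(x, train))
      m$params[[nm]][ii] <- p0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - m$grads[[nm]][ii]))
    }
  }
  worst
}

zero_grads_leaf <- function(m) {
  for (nm in names(m$params)) m$grads[[nm]] <- m$params[[nm]] * 0
}

# write a MATLAB v5 cell-array file using scipy as an independent oracle
write_mat_oracle <- function(path, cells, compress = FALSE) {
  script <- tempfile(fileext = ".py")
  data_file <- tempfile(fileext = ".csv")
  # serialize the cells as csv blocks: one line "rows cols" then the values
  con <- file(data_file, "w")
  writeLines(as.character(length(cells)), con)
  for (m in cells) {
    writeLines(paste(nrow(m), ncol(m)), con)
    writeLines(paste(sprintf("%.17g", as.vector(t(m))), collapse = ","), con)
  }
  close(con)
  writeLines(sprintf("
import numpy as np, scipy.io
with open(%s) as f:
    n = int(f.readline())
    cells = np.empty((1, n), dtype=object)
    for i in range(n):
        r, c = map(int, f.readline().split())
        vals = np.array([float(v) for v in f.readline().split(',')])
        cells[0, i] = vals.reshape(r, c)
scipy.io.savemat(%s, {'p': cells}, do_compression=%s)
", deparse(data_file), deparse(path), if (compress) "True" else "False"),
    script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) {
    stop("oracle .mat writer failed: ", paste(status, collapse = "\n"))
  }
  invisible(path)
}

# Table of BHS grading thresholds published percentages for seven model
# variants (SBP/DBP/MBP rows each) with their printed grades, used as a
# grading oracle.
published_bhs_table <- function() {
  tibble::tribble(
    ~model, ~task, ~p5, ~p10, ~p15, ~grade,
    1, "SBP", 62.08, 80.52, 89.88, "C",
    1, "DBP", 78.16, 92.83, 97.03, "A",
    1, "MBP", 81.30, 94.65, 97.66, "A",
    2, "SBP", 72.58, 88.16, 94.38, "B",
    2, "DBP", 83.85, 94.11, 98.16, "A",
    2, "MBP", 85.49, 95.04, 97.94, "A",
    3, "SBP", 76.37, 89.63, 95.18, "A",
    3, "DBP", 84.93, 94.86, 97.96, "A",
    3, "MBP", 86.59, 94.99, 97.61, "A",
    4, "SBP", 79.09, 89.96, 94.95, "A",
    4, "DBP", 84.54, 94.26, 97.86, "A",
    4, "MBP", 86.08, 94.85, 97.86, "A",
    5, "SBP", 78.71, 89.91, 95.57, "A",
    5, "DBP", 85.95, 95.34, 98.22, "A",
    5, "MBP", 86.18, 94.77, 97.75, "A",
    6, "SBP", 79.93, 89.63, 95.45, "A",
    6, "DBP", 85.54, 94.84, 98.14, "A",
    6, "MBP", 87.06, 95.38, 97.76, "A",
    7, "SBP", 81.44, 90.38, 95.79, "A",
    7, "DBP", 85.46, 94.39, 98.00, "A",
    7, "MBP", 87.22, 95.07, 97.73, "A"
  )
}
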