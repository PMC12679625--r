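# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# A minimal six-marker set whose CoM/CoP surrogates are fully controlled.
# `com_ml` drives the pelvis markers (plus symmetric offsets); heels sit at
# +/- `heel_off` so the CoP surrogate is exactly zero.
make_marker_fixture <- function(n = 1200, rate = 120,
                                com_ml = 0.02 * sin(2 * pi * (0:(n - 1)) / rate),
                                heel_off = 0.1) {
  time <- (0:(n - 1)) / rate
  dat <- tibble::tibble(time = time)
  off <- c(RASI = 0.115, LASI = -0.115, RPSI = 0.095, LPSI = -0.095)
  for (nm in names(off)) {
    dat[[paste0(nm, "_x")]] <- com_ml + off[[nm]]
    dat[[paste0(nm, "_y")]] <- 1.2 * time
    dat[[paste0(nm, "_z")]] <- rep(0.95, n)
  }
  for (nm in c("RHEE", "LHEE")) {
    s <- if (nm == "RHEE") 1 else -1
    dat[[paste0(nm, "_x")]] <- rep(s * heel_off, n)
    dat[[paste0(nm, "_y")]] <- 1.2 * time + s * 0.05
    dat[[paste0(nm, "_z")]] <- rep(0.02, n)
  }
  marker_set(dat, rate = rate)
}

# Scalar trajectory at a given stage without running the pipeline.
make_traj <- function(value, rate = 120, stage = "raw", ...) {
  out <- scalar_traj(value, rate = rate, ...)
  attr(out, "stage") <- stage
  out
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
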