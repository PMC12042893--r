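# Shared builders for tiny in-code fixtures.

# tracts x days logical matrix with proper dimnames
flagMatrix <- function(m, start = "2006-01-01", ids = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  if (is.null(ids)) ids <- sprintf("T%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, format(seq(as.Date(start), by = "day",
                                      length.out = ncol(m))))
  m
}

# numeric tract-day matrix with the same dimname conventions
valueMatrix <- function(m, start = "2006-01-01", ids = NULL) {
  m <- as.matrix(m)
  if (is.null(ids)) ids <- sprintf("T%02d", seq_len(nrow(m)))
  dimnames(m) <- list(ids, format(seq(as.Date(start), by = "day",
                                      length.out = ncol(m))))
  m
}

# hand-built TractSet on a unit lattice; shares fixed and easy to check
toyTracts <- function(n = 4, population = NULL, shares = NULL,
                      states = NULL, svi = NULL, tribal = NULL) {
  if (is.null(population)) population <- rep(1000, n)
  if (is.null(states)) states <- rep("S01", n)
  if (is.null(svi)) {
    svi <- rep(NA_real_, n)
    pop <- population > 0
    svi[pop] <- rank(seq_len(n)[pop]) / sum(pop)
  }
  if (is.null(tribal)) tribal <- rep(FALSE, n)
  base <- data.frame(
    tract_id = sprintf("T%02d", seq_len(n)),
    state = states, county = paste0(states, "-C01"),
    xmin = -120 + (seq_len(n) - 1) * 0.2, xmax = -120 + seq_len(n) * 0.2,
    ymin = 38, ymax = 38.2,
    ix = seq_len(n), iy = 1L,
    population = population,
    hispanic = 0.3, nh_white = 0.5, nh_black = 0.04, nh_asian = 0.08,
    nh_aian = 0.02, nh_other = 0.06,
    svi = svi,
    pct_65plus = 16.8, pct_disability = 12.7, pct_poverty150 = 19.4,
    tribal_overlap = tribal, coastal = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(shares)) base[, colnames(shares)] <- shares
  new("TractSet", tracts = base, latticeDim = c(as.integer(n), 1L))
}

# brute-force coexposure oracle: literal triple loop over the window rule
oracleCoexpose <- function(eh, wfbz, wfs, window) {
  n <- nrow(eh); d <- ncol(eh)
  haz <- list(eh = eh, wfbz = wfbz, wfs = wfs)
  near <- function(m, i, j) {
    any(m[i, max(1, j - 1):min(d, j + 1)])
  }
  pair <- function(a, b) {
    out <- matrix(FALSE, n, d, dimnames = dimnames(eh))
    for (i in seq_len(n)) for (j in seq_len(d)) {
      out[i, j] <- if (window == "same_day") a[i, j] && b[i, j]
      else (a[i, j] && near(b, i, j)) || (b[i, j] && near(a, i, j))
    }
    out
  }
  trip <- if (window == "same_day") haz$eh & haz$wfbz & haz$wfs
          else pair(haz$eh, haz$wfbz) & pair(haz$eh, haz$wfs) &
               pair(haz$wfbz, haz$wfs)
  list(eh_wfbz = pair(haz$eh, haz$wfbz), eh_wfs = pair(haz$eh, haz$wfs),
       wfbz_wfs = pair(haz$wfbz, haz$wfs), eh_wfbz_wfs = trip)
}

# exact Mann-Kendall p-value by exhaustive permutation of the observed
# values (two-sided: P(|S| >= |S_obs|) under random ordering)
exactMKPermutation <- function(x) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k]))
        out[[length(out) + 1L]] <- c(v[k], rest)
    out
  }
  Sof <- function(v) {
    s <- 0
    for (i in seq_len(length(v) - 1))
      s <- s + sum(sign(v[(i + 1):length(v)] - v[i]))
    s
  }
  sObs <- Sof(x)
  all <- vapply(perms(x), Sof, 0)
  mean(abs(all) >= abs(sObs))
}
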