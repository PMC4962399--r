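# In-code fixtures and independent oracles shared across test files.

# A minimal single-plate well table (one replicate) built directly, without
# going through the CSV readers.
make_plate <- function(test_values, pos_values = numeric(0),
                       neg_values = numeric(0), plate_id = "P1",
                       replicate = 1L, statuses = NULL) {
  n_test <- length(test_values)
  layout <- plate_layout_96(n_test = n_test, n_pos = length(pos_values),
                            n_neg = length(neg_values))
  occ <- layout[layout$role != "empty", ]
  fl <- c(pos_values, neg_values, test_values)
  df <- data.frame(
    plate_id = plate_id,
    well = occ$well,
    role = occ$role,
    compound_id = ifelse(occ$role == "positive_control", "riluzole",
                         ifelse(occ$role == "negative_control", "vehicle",
                                paste0("CMP", seq_len(nrow(occ))))),
    dose_um = ifelse(occ$role == "negative_control", 0, 10),
    status = if (is.null(statuses)) "ok" else statuses,
    fluorescence = fl,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  df$fluorescence[df$status != "ok"] <- NA_real_
  screen_dataset(df)
}

# Independent brute-force oracle for the per-well SSMD* score: explicit
# sort-based median and MAD, no calls into the package's scoring path.
oracle_ssmd_star <- function(x, ref, constant = sqrt(2)) {
  sort_median <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
  }
  med <- sort_median(ref)
  mad_raw <- sort_median(abs(ref - med))
  (x - med) / (constant * 1.4826 * mad_raw)
}

# Independent brute-force control-group SSMD: enumerate pairwise differences.
oracle_ssmd_controls <- function(pos, neg) {
  d <- numeric(0)
  for (p in pos) for (q in neg) d <- c(d, p - q)
  m <- sort(d)
  n <- length(m)
  med <- if (n %% 2L == 1L) m[(n + 1L) / 2L] else (m[n / 2L] + m[n / 2L + 1L]) / 2
  med / sqrt(sum((d - mean(d))^2) / (n - 1L))
}

# Write a plate map + readings CSV pair for a dataset; returns the paths.
write_fixture_csvs <- function(dataset, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  map <- file.path(dir, "map.csv")
  rd <- file.path(dir, "readings.csv")
  write_screen(dataset, map, rd)
  list(map = map, readings = rd, dir = dir)
}
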