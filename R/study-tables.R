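#' Sample-tree inventory of the boreal Scots pine campaign
#'
#' The eleven instrumented Scots pines (five young, six old) of the
#' July 2018 Hyytiala campaign in southern Finland: age, height and
#' diameter at breast height as published. Used as fixed inputs to the
#' height regressions and the summary checks.
#'
#' @return data.frame: `tree_id`, `age_group`, `age_yr`, `height_m`,
#'   `dbh_cm`.
#' @export
pine_tree_info <- function() {
  data.frame(
    tree_id = c("Y1", "Y2", "Y3", "Y4", "Y5",
                "O1", "O2", "O3", "O4", "O5", "O6"),
    age_group = c(rep("young", 5), rep("old", 6)),
    age_yr = c(52, 52, 50, 50, 52, 161, 177, 133, 132, 137, 154),
    height_m = c(18.1, 20.9, 16.0, 17.1, 20.4,
                 33.3, 31.0, 36.8, 33.7, 35.9, 34.8),
    dbh_cm = c(20.5, 23.9, 18.5, 17.3, 22.3,
               48.6, 43.0, 47.3, 49.2, 46.6, 51.5)
  )
}

#' Published posterior-mode estimates of the campaign fit
#'
#' The maximum a posteriori estimates reported for the eleven trees:
#' age-group stomatal parameters (lambda, iota, gamma) and per-tree
#' leaf-sapwood area ratios (rho) and time lags (chi, minutes). These
#' are fixture INPUTS here — e.g. for the sensitivity surfaces and the
#' height regressions — not outputs this package can reproduce without
#' the undeposited field data.
#'
#' @return list with `groups` (data.frame: age_group, lambda, iota,
#'   gamma) and `trees` (data.frame: tree_id, rho, chi_min).
#' @export
pine_map_estimates <- function() {
  list(
    groups = data.frame(
      age_group = c("young", "old"),
      lambda = c(2.182e-3, 1.124e-3),
      iota = c(1.200, 0.520),
      gamma = c(2.594e-3, 2.625e-3)
    ),
    trees = data.frame(
      tree_id = c("Y1", "Y2", "Y3", "Y4", "Y5",
                  "O1", "O2", "O3", "O4", "O5", "O6"),
      rho = c(6003, 4774, 4100, 6493, 5551,
              4172, 4084, 5926, 3728, 3317, 2564),
      chi_min = c(104.5, 105.1, 104.2, 74.3, 70.4,
                  165.8, 122.7, 164.7, 174.7, 165.5, 168.5)
    )
  )
}
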