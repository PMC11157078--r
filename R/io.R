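# Readers for the delimited-text formats the synthetic generators write
# (and that instrument dumps are expected to follow).

#' Read an indenter force-displacement stream
#'
#' @param path CSV with columns `t_s`, `delta_mm`, `force_n` (or the
#'   long-form names `time_s`, `displacement_mm`, `force_N`).
#' @return A tibble ready for [clean_record()].
#' @export
read_force_stream <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  nm <- c(time_s = "t_s", displacement_mm = "delta_mm", force_N = "force_n")
  hit <- names(d) %in% names(nm)
  names(d)[hit] <- nm[names(d)[hit]]
  assert_that(all(c("delta_mm", "force_n") %in% names(d)),
              "expected displacement and force columns")
  d
}

#' Read a ToF frame stream
#'
#' @param path CSV with columns `side`, `t_s`, `row`, `col`, `distance_mm`
#'   (as written by [build_experiment_suite()]).
#' @return A frame tibble for [preprocess_frames()].
#' @export
read_tof_frames <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  assert_that(all(c("side", "t_s", "row", "col", "distance_mm") %in% names(d)),
              "malformed frame stream file")
  d
}

#' Read an sEMG trace
#'
#' @param path CSV with columns `t_s`, `uv`.
#' @return A trace tibble for [filter_semg()].
#' @export
read_semg_trace <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  assert_that(all(c("t_s", "uv") %in% names(d)), "malformed sEMG trace file")
  d
}
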