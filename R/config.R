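#' Default run configuration
#'
#' Aggregates every analysis cutoff in one validated list. Defaults are the
#' published thresholds of the procedure: CPM filters of 1 (protein-coding)
#' and 0.5 (lncRNA) required in at least half of the samples; DE calling at
#' |log2FC| > 0.2 (coding) or > 0.15 (non-coding) with BH-adjusted p < 0.05;
#' Pearson co-expression edges at |r| > 0.6, p < 0.05; top/bottom quartile CV
#' strata; and the top-20% exosome detectability filter.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    cpm_coding = 1,          # CPM filter threshold, protein-coding genes
    cpm_lnc = 0.5,           # CPM filter threshold, lncRNA genes
    frac_samples = 0.5,      # fraction of samples that must pass the CPM filter
    lfc_coding = 0.2,        # |log2FC| calling threshold, coding (strict >)
    lfc_lnc = 0.15,          # |log2FC| calling threshold, non-coding (strict >)
    alpha = 0.05,            # BH-adjusted p threshold for DE calls
    corr_r = 0.6,            # |Pearson r| threshold for lncRNA-mRNA edges (strict >)
    corr_p = 0.05,           # p threshold for edges (strict <)
    quantile = 0.25,         # CV stratum width (top/bottom quantile)
    exo_top_frac = 0.2,      # exosome detectability: top fraction by count
    min_library_size = 0,    # drop samples below this aligned-read floor (0 = off)
    pseudocount = 1,         # pseudocount for the log2(CPM + k) transform
    rng_seed = 1L
  ), class = c("run_config", "list"))
}

.cfg_fraction_keys <- c("frac_samples", "quantile", "exo_top_frac")
.cfg_unit_keys <- c("alpha", "corr_p")
.cfg_nonneg_keys <- c("cpm_coding", "cpm_lnc", "lfc_coding", "lfc_lnc",
                      "min_library_size")

#' Validate a run configuration
#'
#' @param cfg a named list of configuration values.
#' @return The validated `run_config`.
#' @export
validate_config <- function(cfg) {
  for (k in .cfg_fraction_keys) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      stop(sprintf("config key '%s' must be a fraction in (0,1), got %s", k, cfg[[k]]))
    }
  }
  for (k in .cfg_unit_keys) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1) {
      stop(sprintf("config key '%s' must lie in (0,1), got %s", k, cfg[[k]]))
    }
  }
  for (k in .cfg_nonneg_keys) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      stop(sprintf("config key '%s' must be >= 0, got %s", k, cfg[[k]]))
    }
  }
  if (!is.numeric(cfg$corr_r) || cfg$corr_r <= 0 || cfg$corr_r >= 1) {
    stop("config key 'corr_r' must lie in (0,1), got ", cfg$corr_r)
  }
  if (!is.numeric(cfg$pseudocount) || cfg$pseudocount <= 0) {
    stop("config key 'pseudocount' must be > 0, got ", cfg$pseudocount)
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = c("run_config", "list"))
}

#' Load a run configuration from a YAML file
#'
#' Absent keys take the defaults of [default_config()]; unknown keys are an
#' error. An empty or missing-body file yields the defaults.
#'
#' @param path path to a YAML key-value file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  cfg <- default_config()
  vals <- yaml::read_yaml(path)
  if (!is.null(vals)) {
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(vals)] <- vals
  }
  validate_config(cfg)
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
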