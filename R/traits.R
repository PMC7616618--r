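#' Harmonic-mean aggregation of queen mating frequency
#'
#' Species-level effective mating frequencies are combined with the harmonic
#' mean: at low mating frequencies an extra mate changes within-colony
#' relatedness far more than at high frequencies, and the harmonic mean gives
#' small values that extra weight.
#'
#' @param observations numeric vector of effective mating frequencies, all
#'   >= 1.
#' @return the harmonic mean, or `NA_real_` for an empty input.
#' @export
aggregate_mating_frequency <- function(observations) {
  observations <- observations[!is.na(observations)]
  if (length(observations) == 0) return(NA_real_)
  if (any(observations < 1))
    stop("effective mating frequency must be >= 1")
  length(observations) / sum(1 / observations)
}

#' Sample-size-weighted colony size
#'
#' Arithmetic mean of colony-size estimates weighted by the number of colonies
#' each estimate was based on. Missing sample sizes contribute with unit
#' weight so that reports lacking a sample size are kept rather than dropped.
#'
#' @param workers numeric vector of mean worker numbers (> 0).
#' @param sample_size integer vector of colony counts per estimate; `NA`
#'   imputed as 1.
#' @return weighted mean, or `NA_real_` for empty input.
#' @export
aggregate_colony_size <- function(workers, sample_size = NULL) {
  keep <- !is.na(workers)
  workers <- workers[keep]
  if (length(workers) == 0) return(NA_real_)
  if (any(workers <= 0)) stop("colony sizes must be positive")
  if (is.null(sample_size)) sample_size <- rep(1, length(workers))
  else {
    sample_size <- sample_size[keep]
    sample_size[is.na(sample_size)] <- 1
  }
  if (any(sample_size <= 0)) stop("sample sizes must be positive")
  sum(workers * sample_size) / sum(sample_size)
}

#' Coefficient of variation of worker head width
#'
#' Standard deviation of worker head width divided by its mean: a continuous,
#' unit-free measure of worker size variation (division of labour proxy).
#' Uses the sample (n - 1) standard deviation by default.
#'
#' @param head_widths_mm numeric vector of worker head widths (> 0), length
#'   >= 2 to be usable.
#' @param sample_sd logical; use the n - 1 denominator (default) or n.
#' @return CV, or `NA_real_` when fewer than 2 measurements exist.
#' @export
worker_size_cv <- function(head_widths_mm, sample_sd = TRUE) {
  head_widths_mm <- head_widths_mm[!is.na(head_widths_mm)]
  if (length(head_widths_mm) < 2) return(NA_real_)
  if (any(head_widths_mm <= 0)) stop("head widths must be positive")
  s <- stats::sd(head_widths_mm)
  if (!sample_sd) s <- s * sqrt((length(head_widths_mm) - 1) / length(head_widths_mm))
  s / mean(head_widths_mm)
}

#' Number of physical worker castes from morphometric evidence
#'
#' Coding rules: limited size variation or monophasic allometric scaling imply
#' a single caste; non-allometric scaling implies as many castes as there are
#' distinct scaling relationships; with no morphometric evidence the
#' literature count is used directly.
#'
#' @param size_variation `"limited"` or `"present"` (or `NA`).
#' @param scaling `"monophasic_allometric"`, `"non_allometric"`, or `NA`.
#' @param n_scaling_relationships integer, required for non-allometric
#'   scaling.
#' @param literature_caste_count integer fallback.
#' @return integer caste count in 1..4.
#' @export
apply_caste_criteria <- function(size_variation = NA, scaling = NA,
                                 n_scaling_relationships = NA,
                                 literature_caste_count = NA) {
  if (!is.na(size_variation) && size_variation == "limited") {
    if (!is.na(n_scaling_relationships) && n_scaling_relationships > 1)
      stop("contradictory annotation: limited size variation with >1 scaling relationships")
    return(1L)
  }
  if (!is.na(scaling) && scaling == "monophasic_allometric") return(1L)
  if (!is.na(scaling) && scaling == "non_allometric") {
    if (is.na(n_scaling_relationships))
      stop("non-allometric scaling requires n_scaling_relationships")
    return(as.integer(n_scaling_relationships))
  }
  if (is.na(literature_caste_count))
    stop("no usable caste evidence")
  as.integer(literature_caste_count)
}

#' Exclude species with derived life histories
#'
#' Species flagged as supercolonial, socially parasitic (other than temporary
#' social parasites), thelytokous, gamergate-reproducing, or using hybrid
#' caste determination represent secondary reductions or reorganizations of
#' social complexity and are removed before analysis.
#'
#' @param records data frame with a `species` column and a character
#'   `exclusion_flags` column (comma/semicolon-separated flags, `""` or `NA`
#'   for none).
#' @return list with `retained` and `excluded` data frames.
#' @export
apply_exclusions <- function(records) {
  flags <- records$exclusion_flags
  if (is.null(flags)) flags <- rep("", nrow(records))
  flags[is.na(flags)] <- ""
  known <- c("supercolonial", "social_parasite", "thelytokous",
             "gamergate", "hybrid_caste_determination")
  has_flag <- vapply(strsplit(flags, "[,;] *"), function(f) {
    f <- f[nzchar(f)]
    bad <- setdiff(f, c(known, "temporary_social_parasite"))
    if (length(bad) > 0) stop("unknown exclusion flag: ", paste(bad, collapse = ", "))
    any(f %in% known)
  }, logical(1))
  list(retained = records[!has_flag, , drop = FALSE],
       excluded = records[has_flag, , drop = FALSE])
}

#' Binarize colony size and mating frequency
#'
#' Colony size is split at the median (or the 40th/60th quantile in
#' sensitivity variants) computed on the species entering the analysis;
#' values at or below the threshold are "small", above it "large". Mating
#' frequency is split at a fixed threshold (default 2 effective mates: the
#' value at which average worker relatedness is midway between its single-
#' queen extremes).
#'
#' @param table data frame with `colony_size` and/or `mating_frequency`.
#' @param colony_rule `"median"`, `"q40"` or `"q60"`.
#' @param mating_threshold numeric (default 2).
#' @return the table with `colony_size_class` (`small`/`large`),
#'   `mating_class` (`low`/`high`) and attributes recording thresholds.
#' @export
binarize_traits <- function(table, colony_rule = c("median", "q40", "q60"),
                            mating_threshold = 2) {
  colony_rule <- match.arg(colony_rule)
  out <- table
  if (!is.null(table$colony_size)) {
    cs <- table$colony_size
    if (all(is.na(cs))) stop("colony_size entirely missing")
    p <- switch(colony_rule, median = 0.5, q40 = 0.4, q60 = 0.6)
    thr <- stats::quantile(cs, probs = p, na.rm = TRUE, names = FALSE)
    out$colony_size_class <- ifelse(is.na(cs), NA_character_,
                                    ifelse(cs <= thr, "small", "large"))
    attr(out, "colony_size_threshold") <- thr
  }
  if (!is.null(table$mating_frequency)) {
    mf <- table$mating_frequency
    out$mating_class <- ifelse(is.na(mf), NA_character_,
                               ifelse(mf <= mating_threshold, "low", "high"))
    attr(out, "mating_threshold") <- mating_threshold
  }
  out
}

#' Transform traits to the analysis scale
#'
#' Colony size, mating frequency and queen number are log10-transformed;
#' worker-size CV is square-root transformed. Also derives the binary caste
#' coding (`single` vs `multiple`).
#'
#' @param table data frame with any of `colony_size`, `mating_frequency`,
#'   `queen_number`, `worker_cv`, `castes`.
#' @return table with added `log10_colony_size`, `log10_mating_frequency`,
#'   `log10_queen_number`, `sqrt_worker_cv`, `castes_binary` columns.
#' @export
transform_traits <- function(table) {
  out <- table
  chk <- function(x, nm) {
    if (any(!is.na(x) & x <= 0)) stop("non-positive ", nm)
    x
  }
  if (!is.null(table$colony_size))
    out$log10_colony_size <- log10(chk(table$colony_size, "colony size"))
  if (!is.null(table$mating_frequency))
    out$log10_mating_frequency <- log10(chk(table$mating_frequency, "mating frequency"))
  if (!is.null(table$queen_number))
    out$log10_queen_number <- log10(chk(table$queen_number, "queen number"))
  if (!is.null(table$worker_cv)) {
    if (any(!is.na(table$worker_cv) & table$worker_cv < 0)) stop("negative CV")
    out$sqrt_worker_cv <- sqrt(table$worker_cv)
  }
  if (!is.null(table$castes))
    out$castes_binary <- ifelse(is.na(table$castes), NA_character_,
                                ifelse(table$castes > 1, "multiple", "single"))
  out
}

#' Collapse mating/queen categories
#'
#' The obligate-binary scheme merges monandry with facultative polyandry
#' (and monogyny with facultative polygyny), because facultative species can
#' still found monandrous/monogynous colonies; only obligate species have made
#' the irreversible transition.
#'
#' @param category character vector of category labels.
#' @param scheme `"three_level"` (identity) or `"obligate_binary"`.
#' @return recoded character vector.
#' @export
collapse_categories <- function(category, scheme = c("three_level", "obligate_binary")) {
  scheme <- match.arg(scheme)
  valid <- c("monandry", "facultative_polyandry", "obligate_polyandry",
             "monogyny", "facultative_polygyny", "obligate_polygyny")
  bad <- setdiff(category[!is.na(category)], valid)
  if (length(bad) > 0) stop("unknown category: ", paste(unique(bad), collapse = ", "))
  if (scheme == "three_level") return(category)
  ifelse(is.na(category), NA_character_,
         ifelse(category %in% c("obligate_polyandry", "obligate_polygyny"),
                "obligate", "not_obligate"))
}

#' Build the species-level analysis table from observation rows
#'
#' Reads a long table with one row per species-observation and aggregates it
#' into one row per species using the curation rules: harmonic-mean mating
#' frequency, sample-size-weighted colony size, head-width CV, and exclusion
#' of derived life histories. Columns recognized: `species`, `genus`,
#' `castes`, `colony_size` + `colony_size_n`, `mating_frequency`,
#' `queen_number`, `head_width_mm`, `mating_category`, `queen_category`,
#' `exclusion_flags`.
#'
#' @param obs data frame of observation rows (or a path to a TSV/CSV file).
#' @param apply_exclusion_rules logical; drop flagged species (default TRUE).
#' @return one-row-per-species data frame with aggregated raw traits,
#'   transformed columns, and provenance counts (`n_*_obs`).
#' @export
build_species_table <- function(obs, apply_exclusion_rules = TRUE) {
  if (is.character(obs) && length(obs) == 1) {
    sep <- if (grepl("\\.csv$", obs)) "," else "\t"
    obs <- utils::read.delim(obs, sep = sep, stringsAsFactors = FALSE)
  }
  if (is.null(obs$species)) stop("column 'species' is required")
  obs$species <- normalize_species_names(obs$species)
  sp <- sort(unique(obs$species))
  get <- function(nm) if (is.null(obs[[nm]])) rep(NA, nrow(obs)) else obs[[nm]]
  pick1 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA else x[[1]]
  }
  rows <- lapply(sp, function(s) {
    o <- obs[obs$species == s, , drop = FALSE]
    g <- function(nm) if (is.null(o[[nm]])) rep(NA, nrow(o)) else o[[nm]]
    mf <- g("mating_frequency")
    cs <- g("colony_size")
    hw <- g("head_width_mm")
    qn <- g("queen_number")
    data.frame(
      species = s,
      genus = pick1(as.character(g("genus"))),
      castes = pick1(suppressWarnings(as.integer(g("castes")))),
      colony_size = aggregate_colony_size(as.numeric(cs),
                                          suppressWarnings(as.numeric(g("colony_size_n")))),
      mating_frequency = aggregate_mating_frequency(as.numeric(mf)),
      queen_number = if (all(is.na(qn))) NA_real_ else mean(as.numeric(qn), na.rm = TRUE),
      worker_cv = worker_size_cv(as.numeric(hw)),
      mating_category = pick1(as.character(g("mating_category"))),
      queen_category = pick1(as.character(g("queen_category"))),
      exclusion_flags = pick1(as.character(g("exclusion_flags"))),
      n_colony_size_obs = sum(!is.na(cs)),
      n_mating_obs = sum(!is.na(mf)),
      n_head_widths = sum(!is.na(hw)),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (!all(is.na(tab$castes)) && any(!is.na(tab$castes) & !(tab$castes %in% 1:4)))
    stop("castes must be in 1..4")
  if (apply_exclusion_rules) {
    split <- apply_exclusions(tab)
    tab <- split$retained
    attr(tab, "excluded") <- split$excluded$species
  }
  transform_traits(tab)
}

#' Maximal complete-case subset for a set of variables
#'
#' Each analysis uses every species with complete data for its own variables
#' rather than a single globally complete subset.
#'
#' @param table species table.
#' @param vars character vector of required columns.
#' @export
complete_cases_for <- function(table, vars) {
  miss <- setdiff(vars, names(table))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- rowSums(is.na(table[, vars, drop = FALSE])) == 0
  table[ok, , drop = FALSE]
}
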