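#' Specification of a longitudinal rodent cohort
#'
#' Per-group start and final means for body weight, lean mass and fat mass;
#' each animal's weekly trajectory interpolates linearly between its group's
#' endpoint means with additive Gaussian week-to-week noise. Group
#' differences are planted phenomenologically - no physiology is modeled.
#'
#' The default groups reproduce the endpoint means of a 12-week
#' sham-control / ovariectomy (OVX) / OVX + estradiol design: control
#' 18.92 to 28.05 g, OVX 25.41 to 45.09 g, OVX + E2 20.96 to 27.32 g body
#' weight, with lean and fat endpoints on the same study's scale.
#'
#' @param groups A data frame with columns `group`, `bw_start_g`,
#'   `bw_final_g`, `lean_start_g`, `lean_final_g`, `fat_start_g`,
#'   `fat_final_g`; defaults described above.
#' @param n_per_group Animals per group, >= 2. Default 6.
#' @param n_weeks Number of weekly measurements, default 12.
#' @param weekly_noise_sd Gaussian noise on each animal-week weight, g.
#'   Default 1.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups = NULL, n_per_group = 6L, n_weeks = 12L,
                        weekly_noise_sd = 1) {
  if (is.null(groups)) {
    groups <- tibble(
      group = c("control", "OVX", "OVX+E2"),
      bw_start_g = c(18.92, 25.41, 20.96),
      bw_final_g = c(28.05, 45.09, 27.32),
      lean_start_g = c(14.5, 16.0, 15.0),
      lean_final_g = c(18.23, 17.98, 19.55),
      fat_start_g = c(3.5, 8.0, 4.5),
      fat_final_g = c(9.33, 26.22, 3.29)
    )
  }
  groups <- as_tibble(groups)
  need <- c("group", "bw_start_g", "bw_final_g", "lean_start_g",
            "lean_final_g", "fat_start_g", "fat_final_g")
  if (!all(need %in% names(groups))) {
    abort(paste("`groups` needs columns", paste(need, collapse = ", ")))
  }
  if (any(groups[need[-1]] <= 0)) abort("all masses must be positive.")
  stop_if_not_number(n_per_group, "n_per_group", 2)
  stop_if_not_number(n_weeks, "n_weeks", 2)
  stop_if_not_number(weekly_noise_sd, "weekly_noise_sd", 0)
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 n_weeks = as.integer(n_weeks),
                 weekly_noise_sd = weekly_noise_sd),
            class = "cohort_spec")
}

#' Generate a longitudinal cohort table
#'
#' One row per animal-week in tidy form. Noise-free trajectories are exactly
#' linear between the group endpoint means, so with `weekly_noise_sd = 0`
#' every animal in a group is identical and each group's cumulative gain
#' equals final minus start mean. Lean plus fat mass is capped at total body
#' weight per animal-week (scaled down proportionally when noise pushes the
#' sum above it).
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble of class `cohort_table`: `animal_id`, `group`, `week`,
#'   `body_weight_g`, `lean_g`, `fat_g`.
#' @examples
#' coh <- generate_cohort(cohort_spec(weekly_noise_sd = 0))
#' dplyr::count(coh, group)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed_if(seed)
  wk <- seq_len(spec$n_weeks)
  frac <- (wk - 1) / (spec$n_weeks - 1)
  out <- purrr::pmap_dfr(spec$groups, function(group, bw_start_g, bw_final_g,
                                               lean_start_g, lean_final_g,
                                               fat_start_g, fat_final_g, ...) {
    purrr::map_dfr(seq_len(spec$n_per_group), function(a) {
      bw <- bw_start_g + frac * (bw_final_g - bw_start_g)
      lean <- lean_start_g + frac * (lean_final_g - lean_start_g)
      fat <- fat_start_g + frac * (fat_final_g - fat_start_g)
      if (spec$weekly_noise_sd > 0) {
        bw <- pmax(bw + rnorm(length(wk), sd = spec$weekly_noise_sd), 1)
        lean <- pmax(lean + rnorm(length(wk), sd = spec$weekly_noise_sd / 2), 0.5)
        fat <- pmax(fat + rnorm(length(wk), sd = spec$weekly_noise_sd / 2), 0.1)
      }
      over <- lean + fat > bw
      scl <- ifelse(over, bw / (lean + fat), 1)
      tibble(animal_id = sprintf("%s_%02d", group, a), group = group,
             week = wk, body_weight_g = bw,
             lean_g = lean * scl, fat_g = fat * scl)
    })
  })
  class(out) <- c("cohort_table", class(out))
  out
}

#' Cohort summary: start, final and cumulative weight gain per group
#'
#' @param cohort A [generate_cohort()] table.
#' @return A tibble with per-group mean (and SE) starting weight, final
#'   weight, and mean cumulative gain (final minus start per animal).
#' @export
cohort_summary <- function(cohort) {
  cohort <- as_tibble(cohort)
  per_animal <- cohort %>%
    group_by(.data$group, .data$animal_id) %>%
    summarise(start_g = .data$body_weight_g[which.min(.data$week)],
              final_g = .data$body_weight_g[which.max(.data$week)],
              .groups = "drop") %>%
    mutate(gain_g = .data$final_g - .data$start_g)
  per_animal %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(),
              start_mean_g = mean(.data$start_g),
              start_se_g = sd(.data$start_g) / sqrt(dplyr::n()),
              final_mean_g = mean(.data$final_g),
              final_se_g = sd(.data$final_g) / sqrt(dplyr::n()),
              gain_mean_g = mean(.data$gain_g),
              .groups = "drop")
}

#' Mass-weighted omega fatty-acid percentages of a fat blend
#'
#' Given the fat ingredients of a diet with their omega-3/6/9 composition
#' fractions (single values or `[low, high]` ranges, as ingredient
#' datasheets often quote), returns the mass-weighted percentage of each
#' omega class in total fat, as a point estimate (range midpoints) with an
#' interval (range endpoints).
#'
#' @param ingredients A data frame with columns `mass_g` plus, for each
#'   class `k` in 3, 6, 9, either `omega<k>` (a single fraction in `[0,1]`)
#'   or `omega<k>_min` / `omega<k>_max` (a range).
#' @return A tibble with one row per omega class: `omega`, `percent`,
#'   `percent_min`, `percent_max`.
#' @examples
#' diet_omega_fractions(data.frame(
#'   mass_g = c(25, 245),
#'   omega3 = c(0.13, 0),
#'   omega6_min = c(0.55, 0.06), omega6_max = c(0.55, 0.10),
#'   omega9_min = c(0.18, 0.44), omega9_max = c(0.18, 0.47)
#' ))
#' @export
diet_omega_fractions <- function(ingredients) {
  ingredients <- as_tibble(ingredients)
  if (nrow(ingredients) == 0L) abort("`ingredients` must contain at least one row.")
  if (!"mass_g" %in% names(ingredients) || any(ingredients$mass_g <= 0)) {
    abort("`ingredients` needs a positive `mass_g` column.")
  }
  total <- sum(ingredients$mass_g)
  one_class <- function(k) {
    nm <- paste0("omega", k)
    if (nm %in% names(ingredients)) {
      lo <- hi <- ingredients[[nm]]
    } else if (all(paste0(nm, c("_min", "_max")) %in% names(ingredients))) {
      lo <- ingredients[[paste0(nm, "_min")]]
      hi <- ingredients[[paste0(nm, "_max")]]
    } else {
      abort(sprintf("composition for omega-%s missing (need `%s` or `%s_min`/`%s_max`).",
                    k, nm, nm, nm))
    }
    if (any(lo < 0 | hi > 1 | lo > hi)) {
      abort("composition fractions must satisfy 0 <= min <= max <= 1.")
    }
    tibble(omega = paste0("omega", k),
           percent = 100 * sum(ingredients$mass_g * (lo + hi) / 2) / total,
           percent_min = 100 * sum(ingredients$mass_g * lo) / total,
           percent_max = 100 * sum(ingredients$mass_g * hi) / total)
  }
  bind_rows(lapply(c(3, 6, 9), one_class))
}
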