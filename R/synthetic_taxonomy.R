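#' Specify a synthetic taxonomy
#'
#' Describes a balanced-or-ragged synthetic avian taxonomy: orders contain
#' families, families contain genera, genera contain species. A fraction of
#' species is sexually dichromatic and yields two records (male, female);
#' monomorphic species yield one "undefined" record, mirroring how
#' attractiveness units are defined per species x sex.
#'
#' @param n_orders Number of orders (>= 1).
#' @param families_per_order,genera_per_family,species_per_genus A single
#'   count, or a length-2 integer range `c(lo, hi)` sampled uniformly per
#'   parent.
#' @param dichromatic_fraction Proportion of species that are sexually
#'   dichromatic, in `[0, 1]`.
#' @param seed Integer seed; the taxonomy stream is independent of the image
#'   and rating streams.
#' @return An object of class `taxonomy_spec`.
#' @export
taxonomy_spec <- function(n_orders = 2, families_per_order = 2,
                          genera_per_family = 2, species_per_genus = 2,
                          dichromatic_fraction = 0.25, seed = 1L) {
  chk <- function(x, nm) {
    abort_if(!length(x) %in% 1:2 || any(x < 1) || any(x != floor(x)),
             sprintf("%s must be a positive count or range", nm))
  }
  chk(n_orders, "n_orders"); chk(families_per_order, "families_per_order")
  chk(genera_per_family, "genera_per_family")
  chk(species_per_genus, "species_per_genus")
  abort_if(length(n_orders) != 1, "n_orders must be a single count")
  abort_if(dichromatic_fraction < 0 || dichromatic_fraction > 1,
           "dichromatic_fraction must lie in [0, 1]")
  structure(list(n_orders = as.integer(n_orders),
                 families_per_order = as.integer(families_per_order),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 dichromatic_fraction = dichromatic_fraction,
                 seed = as.integer(seed)),
            class = "taxonomy_spec")
}

draw_count <- function(x) if (length(x) == 1) x else sample(x[1]:x[2], 1L)

#' Generate a synthetic taxonomy table
#'
#' Expands a [taxonomy_spec()] into species x sex rows. Genus and species
#' labels are globally unique, so taxonomic nesting is implied by the coding
#' and random-intercept models need no explicit nesting syntax.
#'
#' @param spec A [taxonomy_spec()].
#' @return A tibble with columns `order`, `family`, `genus`, `species_id`,
#'   `sex` (`"male"`/`"female"` for dichromatic species, `"undefined"`
#'   otherwise), `dichromatic`, and `unit` (species x sex identifier).
#' @examples
#' generate_taxonomy(taxonomy_spec(1, 1, 1, 1, dichromatic_fraction = 0))
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "taxonomy_spec"))
  set.seed(sub_seed(spec$seed, "taxonomy"))
  rows <- list(); gi <- 0L; si <- 0L; fi <- 0L
  for (o in seq_len(spec$n_orders)) {
    n_fam <- draw_count(spec$families_per_order)
    for (f in seq_len(n_fam)) {
      fi <- fi + 1L
      n_gen <- draw_count(spec$genera_per_family)
      for (g in seq_len(n_gen)) {
        gi <- gi + 1L
        n_sp <- draw_count(spec$species_per_genus)
        for (s in seq_len(n_sp)) {
          si <- si + 1L
          rows[[length(rows) + 1L]] <- c(o, fi, gi, si)
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  species <- tibble::tibble(
    order = sprintf("order_%02d", m[, 1]),
    family = sprintf("family_%03d", m[, 2]),
    genus = sprintf("genus_%04d", m[, 3]),
    species_id = sprintf("species_%05d", m[, 4]),
    dichromatic = stats::runif(nrow(m)) < spec$dichromatic_fraction
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(species, !.data$dichromatic), sex = "undefined"),
    tidyr::crossing(dplyr::filter(species, .data$dichromatic),
                    sex = c("male", "female"))
  )
  out <- dplyr::arrange(out, .data$species_id, .data$sex)
  out$unit <- paste(out$species_id, out$sex, sep = ":")
  out
}
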