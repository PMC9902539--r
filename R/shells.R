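## Distance-shell partitioning and matched control selection.
##
## Particles are binned by their distance to the nearest milling surface
## into half-open shells [low, high) — e.g. 0-15, 15-30, 30-45, 45-60 nm —
## and each shell gets a same-size control set drawn from particles deeper
## than the shell's upper edge: first matched per tomogram (stage 1), then,
## if a tomogram runs out of deep particles, topped up from the global deep
## pool (stage 2, counted as "fallback" draws).

shell_label <- function(lo, hi) sprintf("%g-%g nm", lo, hi)

#' Assign particles to distance shells
#'
#' Half-open binning `[low, high)` of annotated particles by `depth_nm`.
#' Particles at or beyond the last edge are left unassigned but counted.
#'
#' @param t An annotated particle table (`depth_nm` present).
#' @param edges Strictly increasing shell edges in nm starting at 0,
#'   e.g. `c(0, 15, 30, 45, 60)`.
#' @return An object of class `shell_assignment`: `edges`, `shells` (tibble
#'   `particle_id`, `tomogram_id`, `depth_nm`, `shell`), `n_beyond`, and
#'   empty control bookkeeping to be filled by [select_matched_controls()].
#' @export
#' @examples
#' t <- tibble::tibble(particle_id = as.character(1:3), tomogram_id = "t1",
#'                     x = 0, y = 0, z = 0, depth_nm = c(14.9, 15, 29.9))
#' assign_shells(t, c(0, 15, 30))$counts
assign_shells <- function(t, edges = c(0, 15, 30, 45, 60)) {
  t <- validate_particle_table(t)
  if (!"depth_nm" %in% names(t) || anyNA(t$depth_nm)) {
    abort("all particles must carry a depth_nm annotation.",
          class = "lamellar_validation_error")
  }
  if (length(edges) < 2L || edges[1] != 0 || any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing and start at 0.",
          class = "lamellar_domain_error")
  }
  k <- findInterval(t$depth_nm, edges, rightmost.closed = FALSE)
  n_shell <- length(edges) - 1L
  labels <- shell_label(edges[-length(edges)], edges[-1])
  shells <- tibble(
    particle_id = t$particle_id,
    tomogram_id = t$tomogram_id,
    depth_nm = t$depth_nm,
    shell = ifelse(k >= 1L & k <= n_shell, labels[pmin(k, n_shell)], NA_character_)
  )
  counts <- tibble(
    shell = labels,
    lower = edges[-length(edges)],
    upper = edges[-1],
    n = vapply(labels, function(l) sum(shells$shell == l, na.rm = TRUE), integer(1),
               USE.NAMES = FALSE)
  )
  structure(
    list(edges = edges, shells = shells, counts = counts,
         n_beyond = sum(is.na(shells$shell)),
         controls = NULL,
         fallback_counts = setNames(rep(0L, n_shell), labels),
         seeds = list()),
    class = "shell_assignment"
  )
}

#' @export
print.shell_assignment <- function(x, ...) {
  cat("Shell assignment:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat(sprintf("%d particle(s) beyond the last edge\n", x$n_beyond))
  if (!is.null(x$controls)) {
    cat("controls selected for:", paste(unique(x$controls$shell), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select a matched control set for one shell
#'
#' Stage 1 draws, per tomogram and without replacement, from that tomogram's
#' particles with `depth_nm` greater than the shell's upper edge, up to the
#' tomogram's shell count. Stage 2 fills any shortfall from the global pool
#' of deep particles not already selected; those draws are recorded in
#' `fallback_counts`. The control set always has exactly as many particles
#' as the shell, and every control is deeper than the shell's upper edge.
#'
#' @param t The annotated particle table the assignment was built from.
#' @param assignment A `shell_assignment`.
#' @param shell Shell label (e.g. `"0-15 nm"`) or 1-based shell index.
#' @param seed RNG seed; the same seed reproduces the same selection.
#' @return The updated `shell_assignment` with `controls` rows added.
#' @export
select_matched_controls <- function(t, assignment, shell, seed) {
  t <- validate_particle_table(t)
  stopifnot(inherits(assignment, "shell_assignment"))
  labels <- assignment$counts$shell
  if (is.numeric(shell)) shell <- labels[shell]
  if (!shell %in% labels) {
    abort(sprintf("unknown shell '%s'.", shell), class = "lamellar_key_error")
  }
  upper <- assignment$counts$upper[labels == shell]
  members <- assignment$shells[!is.na(assignment$shells$shell) &
                                 assignment$shells$shell == shell, ]
  if (!nrow(members)) {
    abort(sprintf("shell '%s' is empty; nothing to match.", shell),
          class = "lamellar_domain_error")
  }
  deep <- t[t$depth_nm > upper, ]
  picked <- with_seed(seed, {
    sel <- character()
    ## stage 1: tomogram-matched draws
    for (id in unique(members$tomogram_id)) {
      want <- sum(members$tomogram_id == id)
      pool <- deep$particle_id[deep$tomogram_id == id]
      take <- min(want, length(pool))
      if (take > 0) sel <- c(sel, sample(pool, take))
    }
    ## stage 2: global fallback for the shortfall
    shortfall <- nrow(members) - length(sel)
    fallback <- 0L
    if (shortfall > 0) {
      pool <- setdiff(deep$particle_id, sel)
      if (length(pool) < shortfall) {
        abort(sprintf(
          "control pool exhausted for shell '%s': need %d more, only %d deep particle(s) left.",
          shell, shortfall, length(pool)), class = "lamellar_domain_error")
      }
      sel <- c(sel, sample(pool, shortfall))
      fallback <- shortfall
    }
    list(ids = sel, fallback = fallback)
  })
  ctrl <- t[match(picked$ids, t$particle_id), c("particle_id", "tomogram_id", "depth_nm")]
  ctrl$shell <- shell
  assignment$controls <- dplyr::bind_rows(assignment$controls, ctrl)
  assignment$fallback_counts[[shell]] <- picked$fallback
  assignment$seeds[[shell]] <- seed
  assignment
}

#' Extract shell or control member tables
#'
#' @param assignment A `shell_assignment`.
#' @param shell Shell label or index.
#' @param which `"shell"` or `"control"`.
#' @return Tibble of members (`particle_id`, `tomogram_id`, `depth_nm`).
#' @export
shell_members <- function(assignment, shell, which = c("shell", "control")) {
  which <- match.arg(which)
  labels <- assignment$counts$shell
  if (is.numeric(shell)) shell <- labels[shell]
  if (which == "shell") {
    out <- assignment$shells[!is.na(assignment$shells$shell) &
                               assignment$shells$shell == shell, ]
  } else {
    if (is.null(assignment$controls)) {
      abort("no controls selected yet.", class = "lamellar_domain_error")
    }
    out <- assignment$controls[assignment$controls$shell == shell, ]
  }
  as_tibble(out)
}

#' Particle retention as a function of depth
#'
#' Compares the particles that survived a downstream selection (e.g. 3D
#' classification) with the originally picked set, per depth bin.
#'
#' @param picked Annotated particle table of all picked particles.
#' @param retained Annotated particle table of the surviving subset
#'   (`particle_id`s must be a subset of `picked`'s).
#' @param bin_width Depth bin width in nm.
#' @return Tibble with `depth_lo`, `depth_hi`, `n_picked`, `n_retained`,
#'   `fraction` (NA where nothing was picked).
#' @export
retention_profile <- function(picked, retained, bin_width = 5) {
  picked <- validate_particle_table(picked)
  retained <- validate_particle_table(retained)
  if (!"depth_nm" %in% names(picked) || !"depth_nm" %in% names(retained)) {
    abort("both tables must be depth-annotated.", class = "lamellar_validation_error")
  }
  stray <- setdiff(retained$particle_id, picked$particle_id)
  if (length(stray)) {
    abort(sprintf("%d retained particle(s) absent from the picked table (e.g. %s).",
                  length(stray), stray[1]),
          class = "lamellar_validation_error")
  }
  assert_positive(bin_width, "bin_width")
  top <- max(picked$depth_nm)
  edges <- seq(0, by = bin_width, length.out = ceiling(top / bin_width) + 1L)
  if (max(edges) <= top) edges <- c(edges, max(edges) + bin_width)
  bin <- findInterval(picked$depth_nm, edges, rightmost.closed = FALSE)
  kept <- picked$particle_id %in% retained$particle_id
  n_bins <- length(edges) - 1L
  n_picked <- tabulate(bin, nbins = n_bins)
  n_retained <- tabulate(bin[kept], nbins = n_bins)
  tibble(
    depth_lo = edges[-length(edges)],
    depth_hi = edges[-1],
    n_picked = n_picked,
    n_retained = n_retained,
    fraction = ifelse(n_picked > 0, n_retained / n_picked, NA_real_)
  )
}
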