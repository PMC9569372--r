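## Seeded synthetic-data generators: interactomes with a planted key
## regulator, matched DE tables, small solver instances, and confocal
## stacks with ground truth.  All generators are pure functions of their
## parameters plus seed (the caller's RNG state is saved and restored).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Generate a synthetic two-layer interactome
#'
#' PPI edges come from a preferential-attachment graph (confidences
#' uniform on 0.4--1, emitted as STRING-style 0--1000 scores); each TF
#' draws a regulon size uniformly from \code{regulon_size_range} and
#' samples its targets from a dedicated target-gene pool.
#'
#' @param n_proteins number of protein-coding genes on the PPI layer.
#' @param n_tfs number of transcription factors (subset of the proteins).
#' @param mean_ppi_degree target mean PPI degree.
#' @param regulon_size_range integer range c(lo, hi) of regulon sizes.
#' @param seed integer seed.
#' @param n_targets size of the target-gene pool (default
#'   \code{n_proteins}).
#' @param dir optional directory: writes \code{ppi.tsv} and
#'   \code{regulons.tsv} there.
#' @return list: \code{ppi} (protein1, protein2, combined_score),
#'   \code{regulons} (tf, target, source), \code{proteins}, \code{tfs},
#'   \code{targets}, \code{seed}.
#' @export
gen_interactome <- function(n_proteins, n_tfs, mean_ppi_degree = 4,
                            regulon_size_range = c(5, 20), seed = 1,
                            n_targets = n_proteins, dir = NULL) {
  if (n_tfs > n_proteins) stop_malformed("n_tfs must be <= n_proteins")
  if (n_proteins < 2 || n_tfs < 0 || mean_ppi_degree <= 0)
    stop_malformed("infeasible generator sizes")
  if (n_tfs > 0 && regulon_size_range[1L] < 1)
    stop_malformed("regulon sizes must be positive")
  with_seed(seed, {
    proteins <- sprintf("P%04d", seq_len(n_proteins))
    targets <- sprintf("G%04d", seq_len(n_targets))
    m <- max(1L, round(mean_ppi_degree / 2))
    g <- igraph::sample_pa(n_proteins, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ppi <- data.frame(protein1 = proteins[el[, 1L]],
                      protein2 = proteins[el[, 2L]],
                      combined_score = round(stats::runif(nrow(el), 0.4, 1) * 1000),
                      stringsAsFactors = FALSE)
    tfs <- sort(sample(proteins, n_tfs))
    regs <- if (n_tfs > 0) do.call(rbind, lapply(tfs, function(tf) {
      sz <- sample(seq(regulon_size_range[1L], regulon_size_range[2L]), 1L)
      data.frame(tf = tf, target = sort(sample(targets, min(sz, n_targets))),
                 source = "synthetic", stringsAsFactors = FALSE)
    })) else data.frame(tf = character(), target = character(),
                        source = character(), stringsAsFactors = FALSE)
    out <- list(ppi = ppi, regulons = regs, proteins = proteins, tfs = tfs,
                targets = targets, seed = seed)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(ppi, file.path(dir, "ppi.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(regs, file.path(dir, "regulons.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Generate matched DE tables with a planted key regulator
#'
#' The planted TF is strongly up-regulated in the early contrast; a set
#' fraction of its regulon is up-regulated in the late contrast.  Decoy
#' TFs get weaker early fold changes (or non-significant p values) and
#' lower regulon up-fractions.  All remaining genes form a null
#' background (log2FC ~ Normal(0, background_sd), padj ~ Uniform(0,1)).
#'
#' @param net list from [gen_interactome()].
#' @param planted_tf TF gene symbol; must have a regulon.
#' @param lfc_early_planted planted TF early log2 fold change.
#' @param regulon_up_fraction fraction of the planted regulon up-regulated
#'   late.
#' @param lfc_late_targets late log2 fold change of up targets (small
#'   Gaussian jitter, sd 0.3, is added).
#' @param n_decoys number of decoy TFs.
#' @param background_sd null-background log2FC standard deviation.
#' @param decoy_lfc_range early log2FC range for decoys.  The default is
#'   the value the planted default implies (half the planted effect with
#'   floor 0.5); it is a property of the background biology and stays put
#'   when \code{lfc_early_planted} is varied.
#' @param decoy_up_fraction_range range of decoy regulon up-fractions.
#' @param seed integer seed.
#' @return list: \code{de_early}, \code{de_late} (de_table objects),
#'   \code{truth} (planted_tf, regulon, up_targets, decoys, seed).
#' @export
gen_planted_de <- function(net, planted_tf,
                           lfc_early_planted = 3.0,
                           regulon_up_fraction = 0.9,
                           lfc_late_targets = 4.0,
                           n_decoys = 3,
                           background_sd = 0.3,
                           decoy_lfc_range = c(0.5, 1.5),
                           decoy_up_fraction_range = c(0.1, 0.3),
                           seed = 1) {
  regs <- net$regulons
  planted_tf <- toupper(trimws(planted_tf))
  regulon <- sort(unique(regs$target[toupper(regs$tf) == planted_tf]))
  if (!length(regulon))
    stop_malformed("planted TF '%s' has no regulon", planted_tf)
  with_seed(seed, {
    genes <- sort(unique(c(net$proteins, net$targets)))
    bg <- function() data.frame(
      gene = genes,
      log2FoldChange = stats::rnorm(length(genes), 0, background_sd),
      padj = stats::runif(length(genes)), stringsAsFactors = FALSE)
    early <- bg(); late <- bg()
    rownames(early) <- early$gene; rownames(late) <- late$gene

    decoys <- sort(sample(setdiff(net$tfs, planted_tf),
                          min(n_decoys, length(net$tfs) - 1L)))
    for (d in decoys) {
      early[d, "log2FoldChange"] <- stats::runif(1, decoy_lfc_range[1L],
                                                 decoy_lfc_range[2L])
      early[d, "padj"] <- if (stats::runif(1) < 0.5) 1e-6
        else stats::runif(1, 0.05, 1)
      dreg <- sort(unique(regs$target[regs$tf == d]))
      fup <- stats::runif(1, decoy_up_fraction_range[1L],
                          decoy_up_fraction_range[2L])
      nup <- round(fup * length(dreg))
      if (nup > 0) {
        up <- sample(dreg, nup)
        late[up, "log2FoldChange"] <- lfc_late_targets +
          stats::rnorm(nup, 0, 0.3)
        late[up, "padj"] <- 1e-6
      }
    }
    ## planted signal last so it is never overwritten by a decoy regulon
    early[planted_tf, "log2FoldChange"] <- lfc_early_planted
    early[planted_tf, "padj"] <- 1e-6
    nup <- max(1L, round(regulon_up_fraction * length(regulon)))
    up_targets <- sort(sample(regulon, nup))
    late[up_targets, "log2FoldChange"] <- lfc_late_targets +
      stats::rnorm(nup, 0, 0.3)
    late[up_targets, "padj"] <- 1e-6

    rownames(early) <- rownames(late) <- NULL
    list(de_early = read_de_table(early, contrast = "early"),
         de_late = read_de_table(late, contrast = "late"),
         truth = list(planted_tf = planted_tf, regulon = regulon,
                      up_targets = up_targets, decoys = decoys,
                      seed = seed))
  })
}

#' Generate a small PCST instance for oracle testing
#'
#' Costs uniform on 0.1--2; half the nodes (rounded down) carry prizes
#' uniform on 0--5, the rest are Steiner candidates with prize 0.
#'
#' @param n_nodes at most 12 (exact-solver budget).
#' @param topology \code{"path"}, \code{"star"}, or \code{"random"}
#'   (random spanning tree plus extra edges).
#' @param seed integer seed.
#' @return pcst_instance.
#' @export
gen_small_pcst_instance <- function(n_nodes,
                                    topology = c("random", "path", "star"),
                                    seed = 1) {
  topology <- match.arg(topology)
  if (n_nodes > 12) stop_malformed("n_nodes > 12 exceeds the oracle budget")
  if (n_nodes < 2) stop_malformed("need at least 2 nodes")
  with_seed(seed, {
    nm <- sprintf("N%02d", seq_len(n_nodes))
    el <- switch(topology,
      path = cbind(seq_len(n_nodes - 1L), 2:n_nodes),
      star = cbind(rep(1L, n_nodes - 1L), 2:n_nodes),
      random = {
        ## random spanning tree (each node attaches to an earlier one)
        base <- cbind(vapply(2:n_nodes,
                             function(i) sample.int(i - 1L, 1L), 1L),
                      2:n_nodes)
        extra <- t(utils::combn(n_nodes, 2L))
        have <- paste(pmin(base[, 1L], base[, 2L]),
                      pmax(base[, 1L], base[, 2L]))
        extra <- extra[!(paste(extra[, 1L], extra[, 2L]) %in% have), ,
                       drop = FALSE]
        pick <- stats::runif(nrow(extra)) < 0.25
        rbind(base, extra[pick, , drop = FALSE])
      })
    prize <- rep(0, n_nodes)
    prized <- sample(n_nodes, floor(n_nodes / 2))
    prize[prized] <- stats::runif(length(prized), 0, 5)
    pcst_instance(
      data.frame(gene = nm, layer = "protein", prize = prize,
                 stringsAsFactors = FALSE),
      data.frame(u = nm[el[, 1L]], u_layer = "protein",
                 v = nm[el[, 2L]], v_layer = "protein",
                 cost = stats::runif(nrow(el), 0.1, 2), kind = "ppi",
                 stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic confocal z-stack of ellipsoidal nuclei
#'
#' Nuclei are placed by rejection sampling at pairwise centre distance at
#' least \code{min_center_dist_um}, fully inside the field.  The DAPI
#' channel paints each nucleus at a fixed level; marker channels paint
#' per-nucleus true means drawn from \code{channel_intensity_map} ranges.
#' Planes are Gaussian-blurred (sigma ~0.5 um) and additive Gaussian
#' noise, clipped at zero, is applied.
#'
#' @param n_nuclei number of nuclei.
#' @param radius_range_um semi-axis range (each of the three semi-axes is
#'   drawn uniformly from it).
#' @param min_center_dist_um minimum pairwise centre distance.
#' @param channel_intensity_map named list of c(lo, hi) intensity ranges
#'   for the marker channels.
#' @param noise_sd additive Gaussian noise sd.
#' @param pixel_size_xy um/pixel (default 0.3).
#' @param z_step um (default 1).
#' @param field_um c(x, y, z) field size in um.
#' @param dapi_level DAPI foreground intensity.
#' @param background background intensity on all channels.
#' @param blur_sigma_um in-plane Gaussian blur sigma.
#' @param seed integer seed.
#' @param max_tries placement attempts per nucleus before giving up.
#' @param centers_um optional n x 3 matrix of centres (um); disables the
#'   rejection sampling, e.g. to build touching-pair fixtures at an exact
#'   separation.
#' @param dir optional directory: writes \code{stack.tiff},
#'   \code{stack.tiff.yaml} and \code{truth.csv}.
#' @return list: \code{stack} (zstack), \code{truth} (data.frame with
#'   centres, semi-axes and true channel means), \code{seed}.
#' @export
gen_confocal_stack <- function(n_nuclei = 20,
                               radius_range_um = c(3.5, 5.5),
                               min_center_dist_um = 15,
                               channel_intensity_map = list(
                                 marker = c(100, 500)),
                               noise_sd = 10,
                               pixel_size_xy = 0.3, z_step = 1,
                               field_um = c(100, 100, 30),
                               dapi_level = 500, background = 20,
                               blur_sigma_um = 0.5,
                               seed = 1, max_tries = 2000L,
                               centers_um = NULL, dir = NULL) {
  stopifnot(pixel_size_xy > 0, z_step > 0, all(field_um > 0),
            all(radius_range_um > 0), dapi_level > 0)
  with_seed(seed, {
    nx <- round(field_um[1L] / pixel_size_xy)
    ny <- round(field_um[2L] / pixel_size_xy)
    nz <- round(field_um[3L] / z_step)
    ## draw nuclei
    centers <- matrix(0, 0, 3L); axes <- matrix(0, 0, 3L)
    if (!is.null(centers_um)) {
      centers <- as.matrix(centers_um)
      n_nuclei <- nrow(centers)
      axes <- matrix(stats::runif(3L * n_nuclei, radius_range_um[1L],
                                  radius_range_um[2L]), ncol = 3L)
    }
    tries <- 0L
    while (nrow(centers) < n_nuclei) {
      ax <- stats::runif(3, radius_range_um[1L], radius_range_um[2L])
      margin <- ax + 2 * blur_sigma_um
      if (any(field_um <= 2 * margin))
        stop_malformed("field %s um cannot hold nuclei of radius %g um; try fewer nuclei or a larger field",
                       paste(field_um, collapse = "x"), max(ax))
      cand <- c(stats::runif(1, margin[1L], field_um[1L] - margin[1L]),
                stats::runif(1, margin[2L], field_um[2L] - margin[2L]),
                stats::runif(1, margin[3L], field_um[3L] - margin[3L]))
      ok <- !nrow(centers) ||
        all(sqrt(colSums((t(centers) - cand)^2)) >= min_center_dist_um)
      if (ok) {
        centers <- rbind(centers, cand); axes <- rbind(axes, ax)
      } else {
        tries <- tries + 1L
        if (tries > max_tries)
          stop_malformed("could not place %d nuclei at %g um separation; try fewer nuclei",
                         n_nuclei, min_center_dist_um)
      }
    }
    truth <- data.frame(nucleus = seq_len(n_nuclei),
                        cx_um = centers[, 1L], cy_um = centers[, 2L],
                        cz_um = centers[, 3L],
                        rx_um = axes[, 1L], ry_um = axes[, 2L],
                        rz_um = axes[, 3L])
    truth$true_dapi <- dapi_level
    for (chn in names(channel_intensity_map)) {
      rg <- channel_intensity_map[[chn]]
      truth[[paste0("true_", chn)]] <- stats::runif(n_nuclei, rg[1L], rg[2L])
    }

    chans <- c("dapi", names(channel_intensity_map))
    arrs <- lapply(chans, function(.) array(background, c(ny, nx, nz)))
    names(arrs) <- chans
    xs <- (seq_len(nx) - 0.5) * pixel_size_xy
    ys <- (seq_len(ny) - 0.5) * pixel_size_xy
    zs <- (seq_len(nz) - 0.5) * z_step
    for (i in seq_len(n_nuclei)) {
      xr <- which(abs(xs - centers[i, 1L]) <= axes[i, 1L])
      yr <- which(abs(ys - centers[i, 2L]) <= axes[i, 2L])
      zr <- which(abs(zs - centers[i, 3L]) <= axes[i, 3L])
      dx2 <- ((xs[xr] - centers[i, 1L]) / axes[i, 1L])^2
      dy2 <- ((ys[yr] - centers[i, 2L]) / axes[i, 2L])^2
      dz2 <- ((zs[zr] - centers[i, 3L]) / axes[i, 3L])^2
      inside <- outer(dy2, dx2, "+")
      for (kz in seq_along(zr)) {
        sel <- inside + dz2[kz] <= 1
        if (!any(sel)) next
        for (chn in chans) {
          lvl <- truth[[paste0("true_", chn)]][i]
          pl <- arrs[[chn]][yr, xr, zr[kz]]
          pl[sel] <- lvl
          arrs[[chn]][yr, xr, zr[kz]] <- pl
        }
      }
    }
    sig_px <- blur_sigma_um / pixel_size_xy
    for (chn in chans) {
      for (k in seq_len(nz)) {
        pl <- arrs[[chn]][, , k]
        pl <- as.matrix(EBImage::gblur(EBImage::Image(pl), sigma = sig_px))
        if (noise_sd > 0)
          pl <- pl + stats::rnorm(length(pl), 0, noise_sd)
        arrs[[chn]][, , k] <- pmax(pl, 0)
      }
    }
    st <- zstack(arrs, pixel_size_xy, z_step)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      tp <- file.path(dir, "stack.tiff")
      mx <- max(vapply(arrs, max, 0))
      slices <- unlist(lapply(chans, function(chn)
        lapply(seq_len(nz), function(k) arrs[[chn]][, , k] / mx)),
        recursive = FALSE)
      tiff::writeTIFF(slices, tp, bits.per.sample = 16L)
      yaml::write_yaml(list(pixel_size_xy = pixel_size_xy, z_step = z_step,
                            channels = chans, intensity_scale = mx),
                       paste0(tp, ".yaml"))
      utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    }
    list(stack = st, truth = truth, seed = seed)
  })
}

#' Build a complete planted-regulator scenario
#'
#' Generates an interactome, plants the key regulator (the TF with the
#' largest regulon, emulating a master regulator controlling the most
#' targets), and generates the matched DE tables.
#'
#' @param n_proteins,n_tfs,mean_ppi_degree,regulon_size_range passed to
#'   [gen_interactome()].
#' @param seed global seed; fans out to child seeds per generator.
#' @param ... further arguments to [gen_planted_de()]
#'   (e.g. \code{lfc_early_planted}).
#' @return list: \code{interactome} (assembled), \code{net} (raw tables),
#'   \code{de_early}, \code{de_late}, \code{truth}.
#' @export
planted_scenario <- function(n_proteins = 100, n_tfs = 8,
                             mean_ppi_degree = 4,
                             regulon_size_range = c(5, 20),
                             seed = 1, ...) {
  net <- gen_interactome(n_proteins, n_tfs, mean_ppi_degree,
                         regulon_size_range, seed = child_seed(seed, 1L))
  sizes <- table(net$regulons$tf)
  planted <- names(sizes)[order(-as.integer(sizes), names(sizes))][1L]
  de <- gen_planted_de(net, planted, seed = child_seed(seed, 2L), ...)
  inter <- suppressMessages(assemble_interactome(
    load_ppi(net$ppi, "thousand"), load_regulons(net$regulons)))
  list(interactome = inter, net = net, de_early = de$de_early,
       de_late = de$de_late, truth = de$truth)
}
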