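#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard values: dot density 10
#' per square Angstrom, surface contact cutoffs Sm >= 0.4 and Ov >= 0.08,
#' point-atom cutoff 3.8 Angstrom, nearest-neighbour search radius 3.5
#' Angstrom, node burial maximum 0.3, minimum network size 3 and
#' conserved-link threshold 0.8.
#'
#' @param ... Named overrides of individual entries.
#' @return A named list.
#' @export
pack_config <- function(...) {
  cfg <- list(
    density = 10,
    sm_cut = 0.4,
    ov_cut = 0.08,
    atom_cutoff = 3.8,
    nn_cutoff = 3.5,
    burial_max = 0.3,
    min_network_size = 3,
    conservation_threshold = 0.8,
    probe = 1.4,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  abort_if(length(unknown) > 0,
           paste("unknown config entries:", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  bad <- c("density", "sm_cut", "ov_cut", "atom_cutoff", "nn_cutoff",
           "burial_max", "min_network_size", "conservation_threshold")
  abort_if(any(unlist(cfg[bad]) <= 0), "all cutoffs must be positive")
  cfg
}

#' Run a pipeline command
#'
#' Thin programmatic front end tying the modules together; the shipped
#' `packnet` command-line script (in `inst/cli/`) wraps this function.
#' Commands: `surface` (dot surface + burial tables from a PDB file),
#' `contacts` (directed patch and contact tables), `network` (ASCN/APCN edge
#' lists, GraphML and per-graph statistics), `motifs` (exhaustive motif
#' enumeration, or a motif census of the structure's networks), `geometry`
#' (triplet-clique report), `folddetect` (snet/dnet scores of candidate
#' networks against a signature), `simulate` (write a toy structure). All
#' outputs are deterministic for a fixed seed.
#'
#' @param command One of `"surface"`, `"contacts"`, `"network"`, `"motifs"`,
#'   `"geometry"`, `"folddetect"`, `"simulate"`.
#' @param config Configuration list from [pack_config()].
#' @param pdb Input PDB path (surface/contacts/network/geometry).
#' @param mode `"ascn"` or `"apcn"` for `network`.
#' @param enumerate Motif order to enumerate (for `motifs` without a
#'   structure).
#' @param signature Path to a signature JSON (folddetect).
#' @param candidates Named list of candidate edge-list files or a directory
#'   of `.tsv` edge lists (folddetect).
#' @param layout,n_residues Toy-structure parameters (simulate).
#' @param output_dir Directory for report files; `NULL` suppresses writing.
#' @return A list with `status` (0 on success), `outputs` (paths written) and
#'   `result` (the main in-memory result).
#' @export
run_pipeline <- function(command, config = pack_config(), pdb = NULL,
                         mode = c("ascn", "apcn"), enumerate = NULL,
                         signature = NULL, candidates = NULL,
                         layout = "packed-core", n_residues = 3,
                         output_dir = NULL) {
  command <- match.arg(command, c("surface", "contacts", "network", "motifs",
                                  "geometry", "folddetect", "simulate"))
  mode <- match.arg(mode)
  outputs <- character(0)
  emit <- function(df, name) {
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(output_dir, name)
      utils::write.csv(df, path, row.names = FALSE)
      outputs <<- c(outputs, path)
    }
    invisible(NULL)
  }
  emit_json <- function(x, name) {
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(output_dir, name)
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      outputs <<- c(outputs, path)
    }
    invisible(NULL)
  }

  load_atoms <- function() {
    abort_if(is.null(pdb), paste0("command '", command, "' needs a pdb input"))
    read_structure(pdb)
  }

  result <- switch(
    command,
    surface = {
      atoms <- load_atoms()
      surf <- dot_surface(atoms, density = config$density)
      bur <- burial_ratios(atoms, probe = config$probe,
                           density = config$density)
      emit(surf, "surface.csv")
      emit(bur, "burial.csv")
      list(surface = surf, burial = bur)
    },
    contacts = {
      atoms <- load_atoms()
      surf <- dot_surface(atoms, density = config$density)
      patches <- patch_scores(surf, nn_cutoff = config$nn_cutoff)
      contacts <- residue_contacts(patches, sm_cut = config$sm_cut,
                                   ov_cut = config$ov_cut)
      emit(patches, "patches.csv")
      emit(contacts, "contacts.csv")
      list(patches = patches, contacts = contacts)
    },
    network = {
      atoms <- load_atoms()
      bur <- burial_ratios(atoms, probe = config$probe,
                           density = config$density)
      nets <- if (mode == "apcn") {
        build_apcn(atoms, burial = bur, atom_cutoff = config$atom_cutoff,
                   burial_max = config$burial_max,
                   min_size = config$min_network_size)
      } else {
        surf <- dot_surface(atoms, density = config$density)
        eligible <- bur$residue[bur$burial <= config$burial_max]
        eligible <- intersect(eligible,
                              surf$residue[surf$is_side_chain])
        if (length(eligible) == 0) {
          list()
        } else {
          patches <- patch_scores(surf, nn_cutoff = config$nn_cutoff,
                                  targets = eligible)
          contacts <- residue_contacts(patches, sm_cut = config$sm_cut,
                                       ov_cut = config$ov_cut)
          build_ascn(contacts, min_size = config$min_network_size)
        }
      }
      if (length(nets)) {
        edges <- dplyr::bind_rows(purrr::imap(nets, function(g, i) {
          dplyr::mutate(network_edges(g), network = i)
        }))
        emit(edges, paste0(mode, "_edges.csv"))
        stats <- dplyr::bind_rows(purrr::imap(nets, function(g, i) {
          dplyr::mutate(graph_stats(g), network = i)
        }))
        emit_json(stats, paste0(mode, "_stats.json"))
        if (!is.null(output_dir)) {
          for (i in seq_along(nets)) {
            path <- file.path(output_dir,
                              sprintf("%s_net%02d.graphml", mode, i))
            igraph::write_graph(nets[[i]], path, format = "graphml")
            outputs <- c(outputs, path)
          }
        }
      }
      nets
    },
    motifs = {
      if (!is.null(enumerate)) {
        motifs <- enumerate_motifs(enumerate)
        emit(motifs[, c("identifier", "size", "max_degree")], "motifs.csv")
        motifs
      } else {
        atoms <- load_atoms()
        sub <- run_pipeline("network", config = config, pdb = pdb,
                            mode = mode)
        census <- dplyr::bind_rows(purrr::imap(sub$result, function(g, i) {
          tibble::tibble(network = i, size = igraph::vcount(g),
                         identifier = motif_identifier(g),
                         family = classify_family(g))
        }))
        emit(census, "motif_census.csv")
        census
      }
    },
    geometry = {
      atoms <- load_atoms()
      sub <- run_pipeline("network", config = config, pdb = pdb,
                          mode = "ascn")
      rows <- list()
      for (net in sub$result) {
        tri <- find_induced(net, adj_complete(3))
        for (nodes in tri) {
          res <- atoms[residue_key(atoms$resno, atoms$insert) %in% nodes, ]
          fr <- tryCatch(
            lapply(split(res, residue_key(res$resno, res$insert))[nodes],
                   residue_frame),
            error = function(e) NULL)
          if (is.null(fr)) next
          cls <- tryCatch(
            composition_class(vapply(fr, function(f) f$residue, "")),
            error = function(e) NULL)
          if (is.null(cls)) next
          tg <- triangle_geometry(fr, cls)
          th <- tilt_angles(tg)
          ph <- suppressWarnings(swivel_angles(tg))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            residues = paste(nodes, collapse = "+"),
            class = cls$class,
            r_12 = tg$r[1], r_13 = tg$r[2], r_23 = tg$r[3],
            omega_1 = tg$omega[1], omega_2 = tg$omega[2],
            omega_3 = tg$omega[3],
            theta_1t = th[1], theta_2t = th[2], theta_3t = th[3],
            phi_1s = ph[1], phi_2s = ph[2], phi_3s = ph[3]
          )
        }
      }
      report <- dplyr::bind_rows(rows)
      emit(report, "triplet_geometry.csv")
      report
    },
    folddetect = {
      abort_if(is.null(signature), "folddetect needs a signature JSON path")
      sig <- read_fold_signature(signature)
      if (is.character(candidates) && length(candidates) == 1 &&
            dir.exists(candidates)) {
        files <- list.files(candidates, pattern = "\\.tsv$",
                            full.names = TRUE)
        candidates <- stats::setNames(as.list(files),
                                      sub("\\.tsv$", "", basename(files)))
      }
      abort_if(length(candidates) == 0, "no candidate networks given")
      nets <- purrr::map(candidates, function(f) {
        if (igraph::is_igraph(f)) return(f)
        ed <- utils::read.table(f, header = TRUE, colClasses = "character")
        igraph::graph_from_data_frame(ed[, 1:2], directed = FALSE)
      })
      scores <- score_candidates(sig, nets)
      emit(scores$scores, "fold_scores.csv")
      emit_json(scores$summary, "fold_summary.json")
      scores
    },
    simulate = {
      toy <- gen_toy_structure(layout, n_residues = n_residues,
                               seed = config$seed)
      if (!is.null(output_dir)) {
        dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(output_dir, paste0("toy_", layout, ".pdb"))
        write_structure(toy, path)
        outputs <- c(outputs, path)
      }
      toy
    }
  )
  if (!is.null(output_dir)) {
    emit_json(config, "config_used.json")
  }
  list(status = 0L, outputs = outputs, result = result)
}
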