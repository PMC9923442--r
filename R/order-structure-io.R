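# Persistence of the cached per-shape order structures as a versioned
# TSV so the pipeline tables can be inspected, shipped, or reloaded
# without re-deriving them.

structure_file_version <- "1"

#' Write or read the cached quintet order structures
#'
#' The derived per-shape structures (see [quintet_order_structure()])
#' are serialized as a TSV with columns `shape`, `type`
#' (`eq`/`gt`/`omit`), `i`, `j` (topology indices in the canonical
#' catalog of the shape representative's labels `q1..q5`), preceded by
#' a `# multiroot-order-structures v1` header line recording the
#' derivation parameters. `read_order_structures()` loads such a file
#' into the session cache, so subsequent pipeline calls skip the
#' derivation.
#'
#' @param path File path.
#' @return `write_order_structures()`: the path, invisibly;
#'   `read_order_structures()`: the list of structures, invisibly.
#' @export
write_order_structures <- function(path) {
  shapes <- c("caterpillar", "balanced", "pseudo_caterpillar")
  rows <- list()
  meta <- character(0)
  for (s in shapes) {
    st <- shape_structure(s)
    meta <- c(meta, sprintf("%s:draws=%d,samples=%g", s, st$n_draws,
                            st$n_samples))
    add <- function(m, type) {
      if (nrow(m)) {
        tibble::tibble(shape = s, type = type, i = m[, 1], j = m[, 2])
      }
    }
    rows <- c(rows, list(add(st$E, "eq"), add(st$G, "gt"),
                         add(st$omitted, "omit")))
  }
  tab <- dplyr::bind_rows(rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# multiroot-order-structures v%s %s",
                     structure_file_version, paste(meta, collapse = " ")),
             con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_order_structures
#' @export
read_order_structures <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# multiroot-order-structures v1", header)) {
    abort("not a multiroot order-structure file (or wrong version)")
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(tab$shape)) {
    sub <- tab[tab$shape == s, ]
    pick <- function(type) {
      m <- as.matrix(sub[sub$type == type, c("i", "j")])
      dimnames(m) <- NULL
      if (!nrow(m)) matrix(integer(0), ncol = 2) else m
    }
    st <- structure(list(E = pick("eq"), G = pick("gt"),
                         omitted = pick("omit"),
                         labels = paste0("q", 1:5),
                         n_draws = NA_integer_, n_samples = NA_real_),
                    class = "order_structure")
    .multiroot_cache[[paste0("structure_", s)]] <- st
    out[[s]] <- st
  }
  invisible(out)
}
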