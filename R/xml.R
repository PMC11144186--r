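#' Write metacluster metadata to XML
#'
#' One document with one element per metacluster carrying the published
#' comparison field names verbatim (`DA`, `DAC`, `Percent_DA`,
#' `Percent_DAC`, `Percent_DACF`, `Percent_DACFA`, `Label`, `Fred`,
#' `Fext`, `Pfam_sequences`) plus seed statistics, residue-composition
#' fractions, the mean transmembrane count and the seed region list.
#' A metacluster with no row in `comparisons` (or `property_labels`)
#' gets `UNK` in the corresponding fields, mirroring the convention
#' that `DA` is `UNK` when no dominant architecture was found.
#'
#' @param metaclusters list of metacluster objects (see
#'   [metacluster()]).
#' @param comparisons data.frame from [compare_metaclusters()], keyed
#'   by `mc_id`; may be `NULL`.
#' @param property_labels data.frame from [composition_labels()], keyed
#'   by `mc_id`; may be `NULL`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metacluster_xml <- function(metaclusters, comparisons = NULL,
                                  property_labels = NULL, path) {
  doc <- xml2::xml_new_root("metaclusters")
  cmp_fields <- c("DA", "DAC", "Percent_DA", "Percent_DAC",
                  "Percent_DACF", "Percent_DACFA", "Label", "Fred",
                  "Fext", "Pfam_sequences")
  for (mc in metaclusters) {
    node <- xml2::xml_add_child(doc, "metacluster", id = mc$id)
    st <- mc_statistics(mc)
    xml2::xml_add_child(node, "seed_count", format_xml_num(st[["seed_count"]]))
    xml2::xml_add_child(node, "mean_seed_length",
                        format_xml_num(st[["mean_length"]]))
    xml2::xml_add_child(node, "sd_seed_length",
                        format_xml_num(st[["sd_length"]]))
    prow <- match_record(property_labels, mc$id)
    for (f in c("frac_low_complexity", "frac_coiled_coil",
                "frac_disordered", "mean_tm")) {
      xml2::xml_add_child(node, f, record_field(prow, f))
    }
    crow <- match_record(comparisons, mc$id)
    for (f in cmp_fields) {
      xml2::xml_add_child(node, f, record_field(crow, f))
    }
    seeds_node <- xml2::xml_add_child(node, "seeds")
    if (nrow(mc$seeds) > 0L) {
      for (k in seq_len(nrow(mc$seeds))) {
        xml2::xml_add_child(seeds_node, "seed",
                            protein_id = mc$seeds$protein_id[k],
                            start = as.character(mc$seeds$start[k]),
                            end = as.character(mc$seeds$end[k]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

match_record <- function(df, id) {
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  i <- match(id, df$mc_id)
  if (is.na(i)) NULL else df[i, , drop = FALSE]
}

record_field <- function(row, field) {
  if (is.null(row) || !field %in% names(row)) return("UNK")
  v <- row[[field]][1]
  if (is.na(v)) return("UNK")
  if (is.numeric(v)) format_xml_num(v) else as.character(v)
}

format_xml_num <- function(x) {
  format(x, digits = 10, scientific = FALSE, trim = TRUE)
}

#' Parse a metacluster XML document
#'
#' Inverse of [write_metacluster_xml()]: returns the per-metacluster
#' records and seed regions. Numeric fields come back as numerics;
#' `UNK` becomes `NA` in numeric columns and the string `"UNK"` in
#' character columns.
#'
#' @param path XML path.
#' @return list with `records` (one row per metacluster, all scalar
#'   fields) and `seeds` (named list of region data.frames).
#' @export
read_metacluster_xml <- function(path) {
  doc <- xml2::read_xml(path)
  mcs <- xml2::xml_find_all(doc, "./metacluster")
  num_fields <- c("seed_count", "mean_seed_length", "sd_seed_length",
                  "frac_low_complexity", "frac_coiled_coil",
                  "frac_disordered", "mean_tm", "Percent_DA",
                  "Percent_DAC", "Percent_DACF", "Percent_DACFA",
                  "Fred", "Fext", "Pfam_sequences")
  chr_fields <- c("DA", "DAC", "Label")
  rows <- lapply(mcs, function(node) {
    rec <- list(mc_id = xml2::xml_attr(node, "id"))
    for (f in chr_fields) {
      rec[[f]] <- xml2::xml_text(xml2::xml_find_first(node, paste0("./", f)))
    }
    for (f in num_fields) {
      txt <- xml2::xml_text(xml2::xml_find_first(node, paste0("./", f)))
      rec[[f]] <- if (identical(txt, "UNK")) NA_real_ else as.numeric(txt)
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  seeds <- lapply(mcs, function(node) {
    sn <- xml2::xml_find_all(node, "./seeds/seed")
    if (length(sn) == 0L) {
      return(regions(character(), integer(), integer()))
    }
    regions(xml2::xml_attr(sn, "protein_id"),
            as.integer(xml2::xml_attr(sn, "start")),
            as.integer(xml2::xml_attr(sn, "end")))
  })
  records <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  if (!is.null(records)) names(seeds) <- records$mc_id
  list(records = records, seeds = seeds)
}
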