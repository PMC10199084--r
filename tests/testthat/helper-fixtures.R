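# Shared fixture assemblies used by several test files.

paper_metric_inputs <- function(with_ki_override = TRUE) {
  t1 <- load_fixture("table1")
  prof <- table3_profiles()
  inp <- merge(t1[c("compound_id", "binding_energy", "role")], prof,
               by = "compound_id")
  if (with_ki_override) {
    t4 <- load_fixture("table4")
    inp$ki_override <- t4$ki_uM[match(inp$compound_id, t4$compound_id)] * 1e-6
  }
  inp
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
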