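# Repository endpoint templates for the network transport.
# Placeholders: {accession}, {relpath}.  The manifest endpoint must return
# one "relpath<TAB>size" line per file.  These templates are deployment
# configuration: repository layouts drift, so adjust them here, not in code.
metabolights:
  manifest_url: "https://ftp.ebi.ac.uk/pub/databases/metabolights/studies/public/{accession}/manifest.tsv"
  file_url: "https://ftp.ebi.ac.uk/pub/databases/metabolights/studies/public/{accession}/{relpath}"
workbench:
  manifest_url: "https://www.metabolomicsworkbench.org/data/study_manifest.php?STUDY_ID={accession}"
  file_url: "https://www.metabolomicsworkbench.org/data/file.php?STUDY_ID={accession}&FILE={relpath}"
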