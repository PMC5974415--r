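{
  "comment": [
    "Published per-contrast lists of genes called overexpressed in the four",
    "FA contrasts of the hemideletion study. The source table renders as a",
    "flat gene list, so the column assignment here is a reconstruction:",
    "it assumes a row-major ragged 4-column layout with alphabetically",
    "sorted columns, which is the unique assignment consistent with the",
    "stated per-contrast counts (7/8/3/5) and with Mvp, Sez6l2 and Taok2",
    "being the only genes exclusive to the male FA-increase contrast.",
    "Those two constraints (counts and the male-exclusive triple) are as",
    "published; everything else about the assignment is reconstruction."
  ],
  "male_increase": ["AI467606", "Gdpd3", "Kctd13", "Mvp", "Qprt", "Sez6l2", "Taok2"],
  "male_decrease": ["4930451I11Rik", "AI467606", "Asphd1", "Doc2a", "Ino80e", "Ppp4c", "Qprt", "Spn"],
  "female_increase": ["4930451I11Rik", "AI467606", "Kif22"],
  "female_decrease": ["4930451I11Rik", "AI467606", "Asphd1", "Gdpd3", "Kctd13"]
}
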