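# The 24 anatomical location categories (IASLC/AJCC nodal stations).
- {category_id: st_1R, station_label: "1R"}
- {category_id: st_1L, station_label: "1L"}
- {category_id: st_2R, station_label: "2R"}
- {category_id: st_2L, station_label: "2L"}
- {category_id: st_3A, station_label: "3A"}
- {category_id: st_3P, station_label: "3P"}
- {category_id: st_4R, station_label: "4R"}
- {category_id: st_4L, station_label: "4L"}
- {category_id: st_5, station_label: "5"}
- {category_id: st_6, station_label: "6"}
- {category_id: st_7, station_label: "7"}
- {category_id: st_8, station_label: "8"}
- {category_id: st_9, station_label: "9"}
- {category_id: st_10, station_label: "10"}
- {category_id: st_10R, station_label: "10R"}
- {category_id: st_10L, station_label: "10L"}
- {category_id: st_11R, station_label: "11R"}
- {category_id: st_11L, station_label: "11L"}
- {category_id: st_12R, station_label: "12R"}
- {category_id: st_12L, station_label: "12L"}
- {category_id: st_13R, station_label: "13R"}
- {category_id: st_13L, station_label: "13L"}
- {category_id: st_14R, station_label: "14R"}
- {category_id: st_14L, station_label: "14L"}
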