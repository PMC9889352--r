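phrase	category_id
station 7	st_7
level 7	st_7
subcarinal	st_7
station 4r	st_4R
level 4r	st_4R
right lower paratracheal	st_4R
station 4l	st_4L
left lower paratracheal	st_4L
station 2r	st_2R
right upper paratracheal	st_2R
station 2l	st_2L
left upper paratracheal	st_2L
station 10r	st_10R
right hilar	st_10R
station 10l	st_10L
left hilar	st_10L
station 11r	st_11R
right interlobar	st_11R
station 11l	st_11L
left interlobar	st_11L
station 12r	st_12R
right lobar	st_12R
station 12l	st_12L
left lobar	st_12L
station 5	st_5
subaortic	st_5
aortopulmonary window	st_5
ap window	st_5
station 6	st_6
para-aortic	st_6
station 8	st_8
paraesophageal	st_8
station 9	st_9
pulmonary ligament	st_9
station 1r	st_1R
right low cervical	st_1R
station 1l	st_1L
left low cervical	st_1L
station 3a	st_3A
prevascular	st_3A
station 3p	st_3P
retrotracheal	st_3P
station 13r	st_13R
station 13l	st_13L
station 14r	st_14R
station 14l	st_14L
hilar not otherwise specified	st_10
hilar nos	st_10
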