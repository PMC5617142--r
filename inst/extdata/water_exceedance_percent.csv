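river,n_sites,chemical_id,percent
Fox,9,4-Nonylphenol,
Fox,9,Anthracene,100
Fox,9,Benzo[a]pyrene,50
Fox,9,Bis(2-ethylhexyl) phthalate,
Fox,9,Dichlorvos,
Fox,9,Fluoranthene,29
Fox,9,Pyrene,29
Kewaunee,5,4-Nonylphenol,0
Kewaunee,5,Anthracene,
Kewaunee,5,Benzo[a]pyrene,
Kewaunee,5,Bis(2-ethylhexyl) phthalate,
Kewaunee,5,Dichlorvos,
Kewaunee,5,Fluoranthene,
Kewaunee,5,Pyrene,
Little Calumet,3,4-Nonylphenol,0
Little Calumet,3,Anthracene,100
Little Calumet,3,Benzo[a]pyrene,100
Little Calumet,3,Bis(2-ethylhexyl) phthalate,
Little Calumet,3,Dichlorvos,
Little Calumet,3,Fluoranthene,100
Little Calumet,3,Pyrene,100
North Shore Channel,3,4-Nonylphenol,0
North Shore Channel,3,Anthracene,50
North Shore Channel,3,Benzo[a]pyrene,100
North Shore Channel,3,Bis(2-ethylhexyl) phthalate,
North Shore Channel,3,Dichlorvos,
North Shore Channel,3,Fluoranthene,100
North Shore Channel,3,Pyrene,100
Clinton,5,4-Nonylphenol,
Clinton,5,Anthracene,50
Clinton,5,Benzo[a]pyrene,100
Clinton,5,Bis(2-ethylhexyl) phthalate,
Clinton,5,Dichlorvos,
Clinton,5,Fluoranthene,75
Clinton,5,Pyrene,75
Grand/Maple,6,4-Nonylphenol,0
Grand/Maple,6,Anthracene,0
Grand/Maple,6,Benzo[a]pyrene,33
Grand/Maple,6,Bis(2-ethylhexyl) phthalate,
Grand/Maple,6,Dichlorvos,
Grand/Maple,6,Fluoranthene,20
Grand/Maple,6,Pyrene,20
Saginaw,14,4-Nonylphenol,
Saginaw,14,Anthracene,0
Saginaw,14,Benzo[a]pyrene,63
Saginaw,14,Bis(2-ethylhexyl) phthalate,100
Saginaw,14,Dichlorvos,100
Saginaw,14,Fluoranthene,60
Saginaw,14,Pyrene,75
St. Clair,8,4-Nonylphenol,
St. Clair,8,Anthracene,
St. Clair,8,Benzo[a]pyrene,
St. Clair,8,Bis(2-ethylhexyl) phthalate,
St. Clair,8,Dichlorvos,
St. Clair,8,Fluoranthene,
St. Clair,8,Pyrene,
Cuyahoga,5,4-Nonylphenol,0
Cuyahoga,5,Anthracene,60
Cuyahoga,5,Benzo[a]pyrene,80
Cuyahoga,5,Bis(2-ethylhexyl) phthalate,
Cuyahoga,5,Dichlorvos,
Cuyahoga,5,Fluoranthene,60
Cuyahoga,5,Pyrene,80
Tinkers,9,4-Nonylphenol,33
Tinkers,9,Anthracene,25
Tinkers,9,Benzo[a]pyrene,50
Tinkers,9,Bis(2-ethylhexyl) phthalate,
Tinkers,9,Dichlorvos,100
Tinkers,9,Fluoranthene,44
Tinkers,9,Pyrene,75
Oswegatchie,5,4-Nonylphenol,0
Oswegatchie,5,Anthracene,
Oswegatchie,5,Benzo[a]pyrene,
Oswegatchie,5,Bis(2-ethylhexyl) phthalate,100
Oswegatchie,5,Dichlorvos,
Oswegatchie,5,Fluoranthene,
Oswegatchie,5,Pyrene,
Raquette,6,4-Nonylphenol,0
Raquette,6,Anthracene,0
Raquette,6,Benzo[a]pyrene,100
Raquette,6,Bis(2-ethylhexyl) phthalate,100
Raquette,6,Dichlorvos,
Raquette,6,Fluoranthene,0
Raquette,6,Pyrene,25
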