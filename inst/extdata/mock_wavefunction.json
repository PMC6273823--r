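{"n_basis":6,"overlap":[1,-0.0152762242026219,0.216462019118784,0.0963222939738947,-0.111595952324077,0.164765736494443,-0.0152762242026219,1,-0.00202786507212346,-0.0331569918330617,0.172374830229828,-0.123587868468567,0.216462019118784,-0.00202786507212346,1,0.127561036018133,0.185230301809976,0.0483580841592889,0.0963222939738947,-0.0331569918330617,0.127561036018133,1,0.062068351249492,-0.0463782042014242,-0.111595952324077,0.172374830229828,0.185230301809976,0.062068351249492,1,-0.0613619173040313,0.164765736494443,-0.123587868468567,0.0483580841592889,-0.0463782042014242,-0.0613619173040313,1],"mo_coefficients":{"closed":[-0.439080440171843,0.578981879821851,-0.351618928911619,0.441919038218081,-0.564089391902484,0.12920288781696,0.425379755476292,0.366633979523815,0.35325712962232,0.457432763264019,-0.102333902067838,0.458789226756407,-0.370983138802558,-0.293193739834829,-0.25968688879352,0.542614861133415,0.63632997852623,0.377429510637302,0.435750051096531,0.330969053707369,-0.676752271655617,-0.380974488058076,0.415091353842968,0.371507552779741,0.639110266026889,-0.280683831025301,-0.554084747041426,0.428068877085521,0.0525822835182729,-0.533675926246498,-0.0229477849748717,0.552164518445674,0.178360908480743,0.060514479833409,0.437616058770823,-0.506969007279565]},"density":{"closed":[0.74747913862114,-0.196521892169118,0.60931485099653,0.00108926232596092,0.408299696508517,0.276858376477307,-0.196521892169118,0.939280984207027,-0.148129842427207,0.847147019673264,-0.728233244533194,0.486027701670062,0.60931485099653,-0.148129842427207,0.496852941595909,0.0124085721239179,0.324388654567244,0.233280768638249,0.00108926232596092,0.847147019673264,0.0124085721239179,0.809074338493901,-0.592185442274099,0.533924879340032,0.408299696508517,-0.728233244533194,0.324388654567244,-0.592185442274099,0.657338139138689,-0.239663340442767,0.276858376477307,0.486027701670062,0.233280768638249,0.533924879340032,-0.239663340442767,0.454361881615968]},"basis_to_atom":[1,1,2,2,3,3]}
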