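(((t001:45.492927008724259,(t002:6.39239047886209,t003:6.39239047886209)[&age_interval={5.3497414157672729,7.4472391505628472}]:39.100536529862168)[&age_interval={42.75654840734871,48.962983441102025}]:18.979960113860848,((t004:11.469972922595352,t005:11.469972922595352)[&age_interval={11.283433081827795,12.558901942258879}]:27.105110359708632,(t006:24.095376269539528,(((t007:0.28879375654903439,t008:0.28879375654903439)[&age_interval={0.28009506307570514,0.34589407848343379}]:13.047934373962647,t009:13.336728130511682)[&age_interval={13.299395097433065,14.313443140269539}]:6.9044524111378376,t010:20.24118054164952)[&age_interval={16.890016991711768,22.269163864116706}]:3.8541957278900085)[&age_interval={19.76690480458014,27.554584387450113}]:14.479707012764457)[&age_interval={38.263503274581694,45.999433680814313}]:25.897803840281121)[&age_interval={54.833488975646596,76.6172021434508}]:35.527112877414893,(t011:21.96065505750969,t012:21.96065505750969)[&age_interval={20.500447692970422,23.683000409897765}]:78.039344942490317)[&age_interval={95.722298542968929,101.2957955012098}];
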